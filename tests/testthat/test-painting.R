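test_that("default switch rate follows the 400000/n rule", {
  # worked example of the two-surrogate mosaic experiment
  expect_equal(round(default_switch_rate(2 * 21 * 2 * 28), 3), 170.068)
  expect_equal(default_switch_rate(400000), 1.0)
  expect_equal(default_switch_rate(100), 4000.0)
  expect_error(default_switch_rate(0))
})

test_that("forward-backward matches the exhaustive path-sum oracle", {
  set.seed(42)
  for (rep in 1:6) {
    H <- sample(2:3, 1); L <- sample(2:4, 1)
    donors <- matrix(sample(0:1, H * L, TRUE), H, L)
    rec <- sample(0:1, L, TRUE)
    d <- runif(L - 1, 1e-4, 0.02)
    sw <- runif(1, 10, 200); th <- runif(1, 0.01, 0.3)
    prior <- rep(1 / H, H)
    grp <- seq_len(H) - 1L   # each donor its own group
    res <- driftpainter:::cp_hmm_cpp(donors, rec, d, sw, th, prior, grp,
                                     H, rep(1, L), TRUE, 0L)
    orc <- hmm_oracle(donors, rec, d, sw, th)
    expect_equal(res$loglik, orc$loglik, tolerance = 1e-10)
    expect_equal(unclass(res$site_post), unclass(orc$post),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("per-site posteriors are proper probabilities", {
  p <- toy_panel()
  rows <- driftpainter:::resolve_donor_rows(p, donor_set("all_donors"),
                                            "g1_i1")
  r <- paint_haploid(p, 1L, rows, copy_model_params(50, 0.05),
                     site_posterior = TRUE)
  sums <- rowSums(as.matrix(r$site_posterior[, c("G1", "G2")]))
  expect_true(all(abs(sums - 1) < 1e-8))
})

test_that("a recipient identical to one donor copies it entirely", {
  p <- toy_panel()
  # haploid 1 identical to a donor of the other group; the competing
  # donor differs at every site so no alternative path is penalty-free
  p$haps[1, ] <- p$haps[7, ]   # g2_i1 hap1
  p$haps[3, ] <- 1L - p$haps[7, ]
  rows <- c(7L, 3L)            # one G2, one G1 donor
  r <- paint_haploid(p, 1L, rows, copy_model_params(50, 1e-9))
  f <- r$profile |>
    dplyr::group_by(donor_group) |>
    dplyr::summarise(cm = sum(cm))
  expect_gt(f$cm[f$donor_group == "G2"] / sum(f$cm), 1 - 1e-6)
})

test_that("genome-wide fractions are the length-weighted chromosome mean", {
  p <- toy_panel(n_chrom = 3)
  prof <- paint_panel(p, donor_set("all_donors"),
                      recipients = "g1_i1",
                      params = copy_model_params(80, 0.01))
  g <- genome_profiles(prof)
  manual <- prof |>
    dplyr::group_by(donor_group) |>
    dplyr::summarise(cm = sum(cm)) |>
    dplyr::mutate(f = cm / sum(cm))
  expect_equal(g$f[order(g$donor_group)], manual$f[order(manual$donor_group)])
})

test_that("donor exchangeability: permuting donors permutes outputs", {
  p <- toy_panel()
  rows <- driftpainter:::resolve_donor_rows(p, donor_set("all_donors"),
                                            "g1_i1")
  pars <- copy_model_params(60, 0.02)
  r1 <- paint_haploid(p, 1L, rows, pars)
  r2 <- paint_haploid(p, 1L, rev(rows), pars)
  expect_equal(dplyr::arrange(r1$profile, chrom, donor_group),
               dplyr::arrange(r2$profile, chrom, donor_group),
               tolerance = 1e-12)
})

test_that("raising the switch rate never lengthens average chunks", {
  p <- toy_panel(n_sites = 60)
  rows <- driftpainter:::resolve_donor_rows(p, donor_set("all_donors"),
                                            "g1_i1")
  acl <- vapply(c(20, 80, 320), function(sw) {
    r <- paint_haploid(p, 1L, rows, copy_model_params(sw, 0.05))
    average_chunk_length(r$profile)
  }, numeric(1))
  expect_true(all(diff(acl) < 0))
})

test_that("average chunk length handles the trivial geometries", {
  prof <- tibble::tibble(chrom = "c1", donor_group = "G1",
                         cm = 100, chunks = 1)
  expect_equal(average_chunk_length(prof), 100)
  prof$chunks <- 2
  expect_equal(average_chunk_length(prof), 50)
  prof$chunks <- 0
  expect_error(average_chunk_length(prof), "zero")
})

test_that("sampled copy-paths follow the exact posterior", {
  set.seed(11)
  H <- 2; L <- 3
  donors <- matrix(sample(0:1, H * L, TRUE), H, L)
  rec <- sample(0:1, L, TRUE)
  d <- c(0.01, 0.004); sw <- 60; th <- 0.1
  orc <- hmm_oracle(donors, rec, d, sw, th)
  set.seed(21)
  res <- driftpainter:::cp_hmm_cpp(donors, rec, d, sw, th, rep(0.5, H),
                                   c(0L, 1L), 2L, rep(1, L), FALSE, 20000L)
  key <- apply(orc$paths, 1, paste, collapse = "")
  emp <- table(factor(apply(res$paths, 1, paste, collapse = ""),
                      levels = key)) / 20000
  expect_lt(max(abs(emp - orc$pp)), 0.015)
})

test_that("sample_paintings chunks cover each chromosome exactly", {
  p <- toy_panel()
  sp <- sample_paintings(p, 1L, donor_set("all_donors"),
                         copy_model_params(60, 0.05), n_samples = 3,
                         seed = 14)
  for (s in 1:3) for (ch in unique(p$sites$chrom)) {
    ck <- sp$chunks[sp$chunks$sample == s & sp$chunks$chrom == ch, ]
    span <- range(p$sites$cm[p$sites$chrom == ch])
    expect_equal(min(ck$start_cm), span[1])
    expect_equal(max(ck$end_cm), span[2])
    expect_true(all(abs(sort(ck$start_cm)[-1] -
                          sort(ck$end_cm)[-nrow(ck)]) < 1e-9))
  }
})

test_that("E-M recovers a known switch rate and is monotone", {
  # simulate data from the copying model itself
  set.seed(33)
  H <- 8; L <- 10000; sw_true <- 30; th_true <- 0.02
  donors <- matrix(rbinom(H * L, 1, 0.5), H, L)
  cm <- seq(0, 200, length.out = L)
  d <- diff(cm) / 100
  cur <- sample(H, 1); rec <- integer(L)
  for (l in seq_len(L)) {
    if (l > 1 && runif(1) < 1 - exp(-sw_true * d[l - 1]))
      cur <- sample(H, 1)
    rec[l] <- if (runif(1) < th_true) 1L - donors[cur, l] else donors[cur, l]
  }
  haps <- rbind(rec, rec, donors)
  haps[1, colMeans(haps) %in% c(0, 1)] <- 1L
  panel <- haplotype_panel(
    haps,
    tibble::tibble(chrom = "c1", pos = seq_len(L) * 100L, cm = cm),
    tibble::tibble(id = c("rec", paste0("d", 1:4)),
                   group = c("R", rep("D", 4)),
                   hap1 = c(1L, 3L, 5L, 7L, 9L),
                   hap2 = c(2L, 4L, 6L, 8L, 10L)))
  fit <- fit_copy_model_em(panel, donor_set("include_groups", "D"),
                           recipients = "rec", n_iterations = 10,
                           params = copy_model_params(100, 0.05))
  expect_equal(fit$switch_rate, sw_true, tolerance = 0.25)
  expect_equal(fit$emission_rate, th_true, tolerance = 0.5)
  trace <- attr(fit, "loglik_trace")
  for (tr in split(trace, trace$haploid))
    expect_true(all(diff(tr$loglik) > -1e-6))
})

test_that("E-M drives the emission rate to zero for a perfect copy", {
  p <- toy_panel()
  p$haps[1, ] <- p$haps[7, ]   # both recipient haploids perfect copies
  p$haps[2, ] <- p$haps[9, ]
  panel <- p
  fit <- fit_copy_model_em(panel, donor_set("include_groups", "G2"),
                           recipients = "g1_i1", n_iterations = 8,
                           params = copy_model_params(50, 0.05))
  expect_lt(fit$emission_rate, 1e-3)
})

test_that("group aggregation averages individuals and ignores order", {
  p <- toy_panel(n_per_group = 3)
  prof <- paint_panel(p, donor_set("all_donors"),
                      params = copy_model_params(60, 0.02))
  agg <- aggregate_profiles(prof)
  one <- prof |> dplyr::filter(recipient_group == "G1", chrom == "chr1",
                               donor_group == "G2")
  expect_equal(agg$f[agg$recipient_group == "G1" & agg$chrom == "chr1" &
                       agg$donor_group == "G2"],
               mean(one$f))
  # permutation invariance
  prof2 <- prof[sample(nrow(prof)), ]
  attributes(prof2) <- c(attributes(prof2),
                         attributes(prof)[c("chrom_info", "donor_groups",
                                            "params", "level")])
  class(prof2) <- class(prof)
  agg2 <- aggregate_profiles(prof2)
  expect_equal(as.data.frame(dplyr::arrange(agg, recipient_group, chrom,
                                            donor_group)),
               as.data.frame(dplyr::arrange(agg2, recipient_group, chrom,
                                            donor_group)))
})

test_that("within-group painting shows the bottleneck in chunk lengths", {
  p <- ma_small_panel()
  # matched donor counts: 10 donors from each group
  med_acl <- function(group) {
    ids <- p$samples$id[p$samples$group == group][1:11]
    sub <- panel_subset(p, individuals = ids)
    vals <- vapply(sub$samples$id[1:6], function(id) {
      rows <- driftpainter:::resolve_donor_rows(
        sub, donor_set("include_groups", group), id)
      rows <- rows[seq_len(min(20, length(rows)))]
      s <- sub$samples[sub$samples$id == id, ]
      r <- paint_haploid(sub, s$hap1, rows, copy_model_params(100, 0.0077))
      average_chunk_length(r$profile)
    }, numeric(1))
    stats::median(vals)
  }
  expect_gt(med_acl("Pop5b"), med_acl("Pop5"))
})
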