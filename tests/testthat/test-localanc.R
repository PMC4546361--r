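test_that("E-M source posteriors are proper and favour a perfect match", {
  p <- toy_panel(n_groups = 2, n_per_group = 3, n_chrom = 2, n_sites = 50)
  p$haps[1, ] <- p$haps[9, ]   # recipient hap = a G2 haploid
  post <- persite_posteriors_em(p, 1L, c("G1", "G2"), n_em = 15)
  expect_true(all(abs(post$G1 + post$G2 - 1) < 1e-8))
  expect_gt(mean(post$G2), 0.95)
})

test_that("Bayes recalibration follows the stated confusion algebra", {
  raw <- tibble::tibble(haploid = 1L, chrom = "c", site = 1:3,
                        A = c(1, 0, 0.5), B = c(0, 1, 0.5))
  class(raw) <- c("source_posterior", class(tibble::tibble()))
  attr(raw, "sources") <- c("A", "B")

  # rows: copied group X; columns: true group D. f_A^A = 0.8, f_A^B = 0.4
  conf <- matrix(c(0.8, 0.2, 0.4, 0.6), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  betas <- c(A = 0.5, B = 0.5)
  out <- persite_posteriors_nnls(raw, conf, betas)
  # raw Pr(copy A) = 1 -> Pr(A) = 0.8 / (0.8 + 0.4) = 2/3
  expect_equal(out$A[1], 2 / 3)
  expect_true(all(abs(out$A + out$B - 1) < 1e-12))

  # identity confusion leaves posteriors unchanged
  id <- diag(2); dimnames(id) <- dimnames(conf)
  out2 <- persite_posteriors_nnls(raw, id, betas)
  expect_equal(out2$A, raw$A)

  conf0 <- matrix(c(0, 1, 0, 1), 2, dimnames = dimnames(conf))
  expect_error(persite_posteriors_nnls(raw, conf0, betas), "denominator")
})

test_that("segment calling respects thresholds and run lengths", {
  mk_post <- function(p) {
    d <- tibble::tibble(haploid = 1L, chrom = "c", site = seq_along(p),
                        A = p, B = 1 - p)
    class(d) <- c("source_posterior", class(tibble::tibble()))
    attr(d, "sources") <- c("A", "B")
    d
  }
  seg <- call_segments(mk_post(rep(0.95, 100)), "A", 0.94, 100)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start_idx, seg$end_idx, seg$n_snps), c(0, 100, 100))

  expect_equal(nrow(call_segments(mk_post(rep(0.95, 99)), "A", 0.94, 100)), 0)
  # ties are excluded (strictly greater)
  expect_equal(nrow(call_segments(mk_post(rep(0.94, 100)), "A", 0.94, 10)), 0)
  expect_error(call_segments(mk_post(0.9), "A", 0.4, 10), "threshold")
})

test_that("segment calling equals a linear-scan oracle on random input", {
  set.seed(17)
  for (rep in 1:5) {
    p <- runif(300)
    d <- tibble::tibble(haploid = 1L, chrom = "c", site = 1:300,
                        A = p, B = 1 - p)
    class(d) <- c("source_posterior", class(tibble::tibble()))
    thr <- runif(1, 0.55, 0.9); mn <- sample(2:10, 1)
    seg <- call_segments(d, "A", thr, mn)
    orc <- segment_oracle(p, thr, mn)
    expect_equal(nrow(seg), length(orc))
    if (length(orc)) {
      om <- do.call(rbind, orc)
      expect_equal(seg$start_idx, om[, 1])
      expect_equal(seg$end_idx, om[, 2])
    }
  }
})

test_that("raising the threshold never lengthens or adds segments", {
  set.seed(23)
  p <- pmin(pmax(stats::filter(runif(400), rep(1 / 5, 5),
                               circular = TRUE), 0), 1)
  d <- tibble::tibble(haploid = 1L, chrom = "c", site = seq_along(p),
                      A = as.numeric(p), B = 1 - as.numeric(p))
  class(d) <- c("source_posterior", class(tibble::tibble()))
  covered <- function(seg) unlist(purrr::map2(seg$start_idx, seg$end_idx,
                                              ~seq(.x + 1, .y)))
  prev <- NULL
  for (thr in c(0.55, 0.65, 0.75)) {
    seg <- call_segments(d, "A", thr, 3)
    if (!is.null(prev)) {
      expect_lte(sum(seg$n_snps), sum(prev$n_snps))
      expect_true(all(covered(seg) %in% covered(prev)))
    }
    # idempotence: calling on the same input again is identical
    expect_identical(seg, call_segments(d, "A", thr, 3))
    prev <- seg
  }
})

test_that("pairwise similarity pools the four haploid pairings", {
  p <- toy_panel(n_groups = 1, n_per_group = 2, n_chrom = 1, n_sites = 30)
  seg <- tibble::tibble(haploid = c(1L, 2L, 3L, 4L), chrom = "chr1",
                        start_idx = 0L, end_idx = 30L, source = "A",
                        n_snps = 30L, min_posterior = 1)
  # identical haplotypes across individuals
  p$haps[3, ] <- p$haps[1, ]; p$haps[4, ] <- p$haps[2, ]
  s <- pairwise_similarity(p, seg, "g1_i1", "g1_i2", "A")
  expect_equal(s$n_snps, 4 * 30)
  hand <- mean(c(p$haps[1, ] == p$haps[3, ], p$haps[1, ] == p$haps[4, ],
                 p$haps[2, ] == p$haps[3, ], p$haps[2, ] == p$haps[4, ]))
  expect_equal(s$phi, hand)

  # complementary alleles: zero similarity
  p$haps[3, ] <- 1L - p$haps[1, ]
  p$haps[4, ] <- 1L - p$haps[2, ]
  p$haps[2, ] <- 1L - p$haps[1, ]  # make all four pairings mismatch
  s0 <- pairwise_similarity(p, seg, "g1_i1", "g1_i2", "A")
  expect_equal(s0$phi, mean(c(p$haps[1, ] == p$haps[3, ],
                              p$haps[1, ] == p$haps[4, ],
                              p$haps[2, ] == p$haps[3, ],
                              p$haps[2, ] == p$haps[4, ])))

  # symmetry and missing-overlap flagging
  expect_equal(pairwise_similarity(p, seg, "g1_i2", "g1_i1", "A")$phi,
               s0$phi)
  seg_none <- seg[seg$haploid %in% c(1L, 2L), ]
  sNA <- pairwise_similarity(p, seg_none, "g1_i1", "g1_i2", "A")
  expect_true(is.na(sNA$phi))
  expect_equal(sNA$n_snps, 0)
})

test_that("hand-drawn partial segments give the hand-counted proportion", {
  haps <- rbind(c(1, 1, 0, 0, 1), c(0, 0, 0, 0, 0),
                c(1, 0, 0, 1, 1), c(0, 0, 0, 0, 0))
  panel <- haplotype_panel(
    haps,
    tibble::tibble(chrom = "c", pos = 1:5 * 10L, cm = 0:4 * 1.0),
    tibble::tibble(id = c("x", "y"), group = "G",
                   hap1 = c(1L, 3L), hap2 = c(2L, 4L)))
  seg <- tibble::tibble(haploid = c(1L, 3L), chrom = "c",
                        start_idx = c(0L, 2L), end_idx = c(4L, 5L),
                        source = "I", n_snps = c(4L, 3L),
                        min_posterior = 1)
  # overlap of hap1 [0,4) and hap3 [2,5): sites 3,4 -> alleles (0,0) vs
  # (0,1): 1 of 2 match; other pairings have no segments
  s <- pairwise_similarity(panel, seg, "x", "y", "I")
  expect_equal(s$n_snps, 2)
  expect_equal(s$phi, 0.5)
})

test_that("introgression ratios divide per pair and summarise per group", {
  sim <- tibble::tibble(
    individual_a = c("a", "a"), individual_b = c("b", "b"),
    group = "G1", source = c("I", "A"), phi = c(0.7, 0.35))
  r <- introgression_ratio(sim, "I", "A")
  expect_equal(r$pairs$ratio, 2)
  sim2 <- dplyr::mutate(sim, phi = c(0.4, 0.4))
  r2 <- introgression_ratio(sim2, "I", "A")
  expect_equal(r2$pairs$ratio, 1)
  sim0 <- dplyr::mutate(sim, phi = c(0.4, 0))
  expect_error(introgression_ratio(sim0, "I", "A"), "zero")
})

test_that("assignment accuracy scores calls against truth", {
  p <- toy_panel(n_groups = 1, n_per_group = 1, n_chrom = 1, n_sites = 40)
  truth <- tibble::tibble(haploid = 1L, chrom = "chr1",
                          start_cm = c(0, 25), end_cm = c(25, 50),
                          source = c("source1", "source2"))
  cm <- p$sites$cm
  n1 <- sum(cm < 25)
  seg_match <- tibble::tibble(haploid = 1L, chrom = "chr1",
                              start_idx = c(0L, n1),
                              end_idx = c(n1, 40L),
                              source = c("source1", "source2"),
                              n_snps = c(n1, 40L - n1), min_posterior = 1)
  acc <- assignment_accuracy(seg_match, truth, p,
                             length_bins = c(0, Inf))
  expect_equal(acc$accuracy, 1)
  seg_flip <- dplyr::mutate(seg_match, source = rev(source))
  acc0 <- assignment_accuracy(seg_flip, truth, p, length_bins = c(0, Inf))
  expect_equal(acc0$accuracy, 0)
  expect_error(assignment_accuracy(seg_match, truth[0, ], p), "empty")
})

test_that("mosaic local-ancestry accuracy rises with segment length", {
  fx <- dating_fixture(901)
  p <- fx$panel
  hap_ids <- c(1L, 2L, 3L, 4L)
  post <- dplyr::bind_rows(lapply(hap_ids, function(h)
    persite_posteriors_em(p, h, fx$src_groups, n_em = 15)))
  class(post) <- c("source_posterior", class(tibble::tibble()))
  attr(post, "sources") <- fx$src_groups

  seg <- call_segments(post, "A", threshold = 0.94, min_snps = 20)
  truth <- fx$mosaic$truth |>
    dplyr::mutate(source = ifelse(source == "source1", "A", "B"))
  acc <- assignment_accuracy(seg, truth, p,
                             length_bins = c(0, 50, 150, Inf))
  acc <- acc[!is.na(acc$accuracy), ]
  expect_true(all(diff(acc$accuracy) >= -0.02))  # non-decreasing trend
  # pooled accuracy at the calling threshold is high
  pooled <- sum(acc$accuracy * acc$n_snps) / sum(acc$n_snps)
  expect_gt(pooled, 0.95)

  # posterior confidence in the true source grows with interval length
  site_tbl <- post |>
    dplyr::mutate(cm = p$sites$cm[site], chrom2 = p$sites$chrom[site])
  tr1 <- truth
  tr1$len <- tr1$end_cm - tr1$start_cm
  long_cut <- stats::median(tr1$len)
  conf <- vapply(c(FALSE, TRUE), function(long) {
    iv <- tr1[(tr1$len >= long_cut) == long & tr1$haploid %in% hap_ids, ]
    vals <- purrr::pmap_dbl(
      list(iv$haploid, iv$chrom, iv$start_cm, iv$end_cm, iv$source),
      function(h, ch, a, b, src) {
        s <- site_tbl[site_tbl$haploid == h & site_tbl$chrom2 == ch &
                        site_tbl$cm >= a & site_tbl$cm < b, ]
        if (nrow(s) == 0) return(NA_real_)
        mean(s[[src]])
      })
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  expect_gt(conf[2], conf[1])
})

test_that("similarity ratios order bottleneck-vs-admixture timing", {
  # A bottleneck after the admixture homogenises introgressed and
  # ancestral segments alike, so the introgressed/ancestral similarity
  # ratio overlaps the non-bottlenecked group's; a bottleneck that
  # predates the admixture homogenises only the ancestral background and
  # pushes the ratio down.
  ratio_for <- function(seed) {
    p <- simulate_panel(
      driftpainter:::new_demography(
        tibble::tibble(name = c("I", "A", "anc"), size = 5000),
        list(driftpainter:::split_ev(2500, c("I", "A"), "anc"))),
      c(I = 12, A = 12), regions = rep(8e6, 3), mutation_rate = 5e-9,
      seed = seed)
    pool_I <- panel_subset(p, individuals = paste0("I_", 1:6))
    pool_A <- panel_subset(p, individuals = paste0("A_", 1:6))
    donors <- panel_subset(p, individuals = c(paste0("I_", 7:12),
                                              paste0("A_", 7:12)))
    mk_group <- function(srcI, srcA, n, s2, prop = 0.2)
      simulate_admixed_mosaic(srcI, srcA, prop, gens = 30,
                              n_haploids = n, seed = s2)
    arc <- mk_group(pool_I, pool_A, 8, seed + 1)
    fnd <- mk_group(pool_I, pool_A, 2, seed + 2)
    fnd_panel <- function(k) {
      h <- fnd$panel$haps[k, , drop = FALSE]
      haplotype_panel(rbind(h, h), fnd$panel$sites,
                      tibble::tibble(id = "f", group = "F",
                                     hap1 = 1L, hap2 = 2L))
    }
    arb_after <- simulate_admixed_mosaic(fnd_panel(1), fnd_panel(2), 0.5,
                                         gens = 30, n_haploids = 8,
                                         seed = seed + 3)
    bnA <- panel_subset(pool_A, individuals = pool_A$samples$id[1])
    arb_before <- mk_group(pool_I, bnA, 8, seed + 4)
    score_group <- function(mos, tag) {
      comb <- haplotype_panel(
        rbind(mos$panel$haps, donors$haps), p$sites,
        dplyr::bind_rows(
          mos$panel$samples,
          dplyr::mutate(donors$samples,
                        hap1 = hap1 + nrow(mos$panel$haps),
                        hap2 = hap2 + nrow(mos$panel$haps))))
      post <- dplyr::bind_rows(lapply(1:8, function(h)
        persite_posteriors_em(comb, h, c("I", "A"), n_em = 10)))
      class(post) <- c("source_posterior", class(tibble::tibble()))
      attr(post, "sources") <- c("A", "I")
      segs <- dplyr::bind_rows(call_segments(post, "I", 0.94, 100),
                               call_segments(post, "A", 0.94, 100))
      prs <- t(utils::combn(mos$panel$samples$id, 2))
      dplyr::bind_rows(lapply(seq_len(nrow(prs)), function(i)
        dplyr::bind_rows(
          pairwise_similarity(comb, segs, prs[i, 1], prs[i, 2], "I"),
          pairwise_similarity(comb, segs, prs[i, 1], prs[i, 2], "A")))) |>
        dplyr::mutate(group = tag)
    }
    sims <- dplyr::bind_rows(score_group(arc, "arc"),
                             score_group(arb_after, "arb_after"),
                             score_group(arb_before, "arb_before"))
    introgression_ratio(sims, "I", "A")$by_group
  }
  res <- dplyr::bind_rows(lapply(c(501, 502, 503), ratio_for)) |>
    dplyr::group_by(group) |>
    dplyr::summarise(med = stats::median(median_ratio),
                     lo = min(q025), hi = max(q975))
  med <- setNames(res$med, res$group)
  expect_gt(med["arb_after"], med["arb_before"])
  # bottleneck-after ratios overlap the non-bottlenecked group's spread
  expect_gte(med["arb_after"], res$lo[res$group == "arc"])
})
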