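test_that("demography presets encode the stated events", {
  ma <- build_demography("MA_full")
  sp <- purrr::keep(ma$splits, ~"Pop5b" %in% .x$derived)[[1]]
  expect_equal(sp$time, 20)
  expect_equal(sp$ancestral, "Pop5")
  expect_equal(unname(ma$populations$size[ma$populations$name == "Pop5b"]),
               200)
  expect_equal(unname(ma$populations$size[ma$populations$name == "Pop5"]),
               20000)

  rn <- build_demography("RN_full")
  sp <- purrr::keep(rn$splits, ~"Pop5b" %in% .x$derived)[[1]]
  expect_equal(sp$time, 1700)
  pl <- purrr::keep(rn$pulses, ~.x$source == "Pop5b" && .x$dest == "Pop5")[[1]]
  expect_equal(pl$rate, 0.005)
  expect_equal(c(pl$time_start, pl$time_end), c(200, 300))

  s <- build_demography("simplified_RN", split = 750)
  expect_equal(s$params$bottleneck_start, 40)
  expect_equal(s$params$bottleneck_size, 5000)
  expect_equal(unname(s$populations$size[s$populations$name == "Pop5b"]),
               5000)

  s17 <- build_demography("simplified_RN", split = 1700, pulse = 0.5)
  expect_equal(s17$params$bottleneck_start, 20)
  pl <- purrr::keep(s17$pulses, ~.x$source == "Pop5b" && .x$dest == "Pop5")[[1]]
  expect_equal(pl$rate, 0.005)
})

test_that("demography rejects unknown presets and off-grid overrides", {
  expect_error(build_demography("bogus"), "valid presets")
  expect_error(build_demography("simplified_RN", split = 650), "one of")
  expect_error(build_demography("simplified_RN", pulse = 0.6), "one of")
  expect_error(build_demography("MA_pop5a", split = 600), "one of")
})

test_that("simulated panels match coalescent expectations", {
  # near-zero differentiation for a split 1 generation ago
  p <- simulate_panel(two_pop_model(ne = 5000, split_gens = 1),
                      c(A = 20, B = 20), regions = rep(1e6, 3), seed = 5)
  expect_lt(abs(hudson_fst(p, "A", "B")), 0.01)

  # mean pairwise diversity per bp ~ 4 N mu in a single population
  mu <- 2e-8; ne <- 5000
  m1 <- driftpainter:::new_demography(
    tibble::tibble(name = "A", size = ne), list())
  pis <- vapply(1:4, function(s) {
    p1 <- simulate_panel(m1, c(A = 15), regions = rep(1e6, 2),
                         mutation_rate = mu, seed = 100 + s)
    f <- colMeans(p1$haps); n <- nrow(p1$haps)
    sum(n / (n - 1) * 2 * f * (1 - f)) / 2e6
  }, numeric(1))
  expect_equal(mean(pis), 4 * ne * mu, tolerance = 0.1)
})

test_that("simulation is reproducible bit-for-bit given a seed", {
  m <- two_pop_model(ne = 2000, split_gens = 500)
  p1 <- simulate_panel(m, c(A = 5, B = 5), regions = rep(5e5, 2), seed = 77)
  p2 <- simulate_panel(m, c(A = 5, B = 5), regions = rep(5e5, 2), seed = 77)
  expect_identical(p1$haps, p2$haps)
  expect_identical(p1$sites, p2$sites)
  p3 <- simulate_panel(m, c(A = 5, B = 5), regions = rep(5e5, 2), seed = 78)
  expect_false(identical(p1$haps, p3$haps))
})

test_that("F_ST increases with split time", {
  fst_at <- function(split, seed) {
    p <- simulate_panel(two_pop_model(ne = 2000, split_gens = split),
                        c(A = 10, B = 10), regions = rep(5e5, 2),
                        seed = seed)
    hudson_fst(p, "A", "B")
  }
  seeds <- 1:10
  f <- vapply(c(200, 1000, 3000), function(s)
    mean(vapply(seeds, function(sd) fst_at(s, 1000 * s + sd), numeric(1))),
    numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("sampling from an extinct population is rejected", {
  m <- two_pop_model()
  expect_error(simulate_panel(m, c(anc = 5), regions = 1e6, seed = 1),
               "absent at time 0")
  expect_error(simulate_panel(m, c(A = 5), regions = 0, seed = 1),
               "positive length")
})

test_that("ascertainment hits exact counts and honours the target spectrum", {
  p <- ma_small_panel()
  a <- ascertain_snps(p, n_per_region = 500, seed = 9)
  counts <- table(a$sites$chrom)
  expect_true(all(counts == 500))
  f <- colMeans(a$haps)
  expect_true(all(f > 0 & f < 1))  # no monomorphic sites survive

  # self-matching: retained spectrum close to the source spectrum
  src <- maf_spectrum(p) / sum(maf_spectrum(p))
  got <- maf_spectrum(a) / sum(maf_spectrum(a))
  expect_lt(max(abs(cumsum(src) - cumsum(got))), 0.05)

  # skewed target: all mass in one abundant bin
  spec <- rep(0, 100); spec[80] <- 1   # MAF [0.395, 0.40)
  a2 <- ascertain_snps(p, target_spectrum = spec, n_per_region = 20,
                       seed = 10)
  maf <- pmin(colMeans(a2$haps), 1 - colMeans(a2$haps))
  expect_true(all(maf >= 0.395 & maf < 0.4))

  expect_error(ascertain_snps(p, rep(0, 100), 10, seed = 1), "not all zero")
})

test_that("bottlenecked population is more internally homogeneous", {
  p <- ma_small_panel()
  ibs <- function(group) {
    rows <- driftpainter:::group_hap_rows(p, group)
    h <- p$haps[rows, ]
    pr <- utils::combn(nrow(h), 2)
    mean(vapply(seq_len(ncol(pr)), function(i)
      mean(h[pr[1, i], ] == h[pr[2, i], ]), numeric(1)))
  }
  expect_gt(ibs("Pop5b"), ibs("Pop5"))
})

test_that("admixture mosaics tile the genome and copy source alleles", {
  p <- toy_panel(n_groups = 2, n_per_group = 4, n_chrom = 2, n_sites = 60)
  src1 <- panel_subset(p, individuals = p$samples$id[p$samples$group == "G1"])
  src2 <- panel_subset(p, individuals = p$samples$id[p$samples$group == "G2"])
  mos <- simulate_admixed_mosaic(src1, src2, 0.5, gens = 30, n_haploids = 6,
                                 seed = 3)
  for (h in 1:6) {
    tr <- mos$truth[mos$truth$haploid == h, ]
    for (ch in unique(tr$chrom)) {
      iv <- tr[tr$chrom == ch, ]
      span <- range(p$sites$cm[p$sites$chrom == ch])
      expect_equal(iv$start_cm[1], span[1])
      expect_equal(iv$end_cm[nrow(iv)], span[2])
      if (nrow(iv) > 1)
        expect_equal(iv$start_cm[-1], iv$end_cm[-nrow(iv)])
    }
  }
  # degenerate mixture: everything from source 1
  mos1 <- simulate_admixed_mosaic(src1, src2, 1.0, gens = 30,
                                  n_haploids = 4, seed = 4)
  expect_true(all(mos1$truth$source == "source1"))

  # reproducibility
  mosa <- simulate_admixed_mosaic(src1, src2, 0.5, 30, 6, seed = 3)
  expect_identical(mos$panel$haps, mosa$panel$haps)
  expect_identical(mos$truth, mosa$truth)
})

test_that("mosaic breakpoint count and ancestry fraction match expectation", {
  # synthetic 100 cM chromosome
  set.seed(8)
  n_sites <- 200
  sites <- tibble::tibble(chrom = "c1", pos = seq_len(n_sites) * 1000L,
                          cm = seq(0, 100, length.out = n_sites))
  mk <- function(seed_off) {
    haps <- matrix(rbinom(8 * n_sites, 1, 0.5), 8, n_sites)
    haps[1, colMeans(haps) %in% c(0, 1)] <- 1L
    samples <- tibble::tibble(id = paste0("i", 1:4), group = "S",
                              hap1 = c(1L, 3L, 5L, 7L),
                              hap2 = c(2L, 4L, 6L, 8L))
    haplotype_panel(haps, sites, samples)
  }
  s1 <- mk(1); s2 <- mk(2)
  mos <- simulate_admixed_mosaic(s1, s2, 0.6, gens = 120, n_haploids = 40,
                                 seed = 12)
  # number of exponential renewals on 100 cM at rate 1.2/cM ~ Poisson(120)
  n_break <- mos$truth |>
    dplyr::count(haploid) |>
    dplyr::pull(n) - 1
  expect_equal(mean(n_break), 120, tolerance = 0.05)
  fr <- truth_source_fractions(mos$truth)
  expect_equal(fr$fraction[fr$source == "source1"], 0.6, tolerance = 0.05)
})
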