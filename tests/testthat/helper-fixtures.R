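# Shared fixtures. Heavy simulated objects are built lazily once per test
# session and cached here; all fixtures are generated in code.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small deterministic panel: `n_chrom` chromosomes of `n_sites` sites each,
# groups of `n_per_group` diploids drawn from distinct allele-frequency
# profiles so groups are separable.
toy_panel <- function(n_groups = 2, n_per_group = 3, n_chrom = 2,
                      n_sites = 40, cm_span = 50, seed = 99) {
  set.seed(seed)
  n_ind <- n_groups * n_per_group
  total_sites <- n_chrom * n_sites
  freqs <- matrix(runif(n_groups * total_sites, 0.1, 0.9),
                  n_groups, total_sites)
  haps <- matrix(0L, 2 * n_ind, total_sites)
  grp <- rep(seq_len(n_groups), each = n_per_group)
  for (i in seq_len(n_ind)) {
    for (h in 0:1)
      haps[2 * i - 1 + h, ] <- as.integer(runif(total_sites) <
                                            freqs[grp[i], ])
  }
  # keep polymorphic columns only (regenerate fixed alleles)
  mono <- colMeans(haps) %in% c(0, 1)
  haps[1, mono] <- 1L - haps[1, mono]
  sites <- tibble::tibble(
    chrom = rep(sprintf("chr%d", seq_len(n_chrom)), each = n_sites),
    pos = rep(seq_len(n_sites) * 1000L, n_chrom),
    cm = rep(seq(0, cm_span, length.out = n_sites), n_chrom))
  samples <- tibble::tibble(
    id = sprintf("g%d_i%d", grp, rep(seq_len(n_per_group), n_groups)),
    group = sprintf("G%d", grp),
    hap1 = seq(1L, by = 2L, length.out = n_ind),
    hap2 = seq(2L, by = 2L, length.out = n_ind))
  haplotype_panel(haps, sites, samples)
}

# Two-population coalescent panel (custom split model).
two_pop_model <- function(ne = 5000, split_gens = 2000) {
  driftpainter:::new_demography(
    tibble::tibble(name = c("A", "B", "anc"), size = ne),
    list(driftpainter:::split_ev(split_gens, c("A", "B"), "anc")))
}

# Small MA-style panel for within-group homogeneity checks.
ma_small_panel <- function(seed = 31) {
  cache_fixture(paste0("ma_small_", seed), function() {
    m <- build_demography("MA_full")
    simulate_panel(m, c(Pop5 = 12, Pop5b = 12), regions = rep(2e6, 3),
                   seed = seed)
  })
}

# Desk-scale marginalisation fixture used by the qualitative signature
# tests: ten 15 cM regions (compressed map), chip-like flat ascertainment,
# paintings under analyses A (Ari recipients only), B and C.
ma_fixture <- function(seed) {
  cache_fixture(paste0("ma_fix_", seed), function() {
    m <- build_demography("MA_full")
    samp <- c(Pop1 = 12, Pop2 = 12, Pop3 = 12, Pop4 = 12, Pop5 = 23,
              Pop5b = 10, Pop6 = 12, Pop7 = 12, Pop8 = 12, Pop9 = 12,
              Pop11 = 12, Pop12 = 12)
    p0 <- simulate_panel(m, samp, regions = rep(3e6, 10),
                         recombination_rate = 5e-8, mutation_rate = 2e-8,
                         seed = seed)
    p <- ascertain_snps(p0, target_spectrum = rep(1, 100),
                        n_per_region = 1200, seed = seed + 1)
    params <- copy_model_params(400, 0.001)
    ari <- p$samples$id[p$samples$group %in% c("Pop5", "Pop5b")]
    # recipients: all Ari plus eight per surrogate group (group averages)
    others <- unlist(lapply(setdiff(panel_groups(p), c("Pop5", "Pop5b")),
                            function(g)
                              p$samples$id[p$samples$group == g][1:8]))
    donors_C <- c("Pop1", "Pop2", "Pop3", "Pop7", "Pop8", "Pop9",
                  "Pop11", "Pop12")
    list(
      panel = p, params = params, ari = ari,
      profA = paint_panel(p, donor_set("all_donors"), recipients = ari,
                          params = params),
      profB = paint_panel(p, donor_set("exclude_groups",
                                       c("Pop5", "Pop5b")),
                          recipients = c(ari, others), params = params),
      profC = paint_panel(p, donor_set("include_groups", donors_C),
                          recipients = c(ari, others), params = params))
  })
}

ma_fixture_seeds <- function() 1:5

# Derived signature quantities per seed, cached so the acceptance test and
# the module-level property tests share one computation.
ma_signature <- function(seed) {
  cache_fixture(paste0("ma_sig_", seed), function() {
    fx <- ma_fixture(seed)
    ari_grp <- c("Pop5", "Pop5b")
    labs <- setNames(fx$panel$samples$group, fx$panel$samples$id)
    cc <- cluster_config(C = 2, delta = 50, M = 20000, burn_in = 10000,
                         thin = 200, n_chains = 5)
    cmpB <- compare_profiles(fx$profB, "group")
    cmpC <- compare_profiles(fx$profC, "group")
    ps <- p_statistic(pairwise_f_matrix(fx$profC, ari_grp),
                      "Pop5", "Pop5b")
    surr <- setdiff(unique(fx$profB$recipient_group), ari_grp)
    apB5 <- ancestry_profile(fx$profB, "Pop5", surrogates = surr)
    apB5b <- ancestry_profile(fx$profB, "Pop5b", surrogates = surr)
    list(
      sepA = label_separation_rate(
        run_gibbs(profiles_subset(fx$profA, ari_grp), cc, seed = seed + 7),
        labs),
      sepB = label_separation_rate(
        run_gibbs(profiles_subset(fx$profB, ari_grp), cc, seed = seed + 7),
        labs),
      cmpB = cmpB, cmpC = cmpC, p5 = ps$p_x, p5b = ps$p_y,
      apB5 = apB5, apB5b = apB5b)
  })
}

# F_XY of the Ari-like pair and the minimum over pairs whose split is
# older than 700 generations.
ma_fxy_margin <- function(cmp) {
  ari_grp <- c("Pop5", "Pop5b")
  f55 <- cmp$f_xy[cmp$x %in% ari_grp & cmp$y %in% ari_grp]
  older <- mapply(ma_pair_split, cmp$x, cmp$y) > 700
  c(f55 = f55, min_older = min(cmp$f_xy[older], na.rm = TRUE))
}

# Split time between two sampled groups of the full simulated world.
ma_pair_split <- function(a, b) {
  ooa <- c("Pop8", "Pop9", "Pop11", "Pop12")
  if (a == "Pop1" || b == "Pop1") return(4000)
  in_ooa <- c(a %in% ooa, b %in% ooa)
  if (xor(in_ooa[1], in_ooa[2])) return(2500)
  if (all(in_ooa)) {
    if (all(c(a, b) %in% c("Pop8", "Pop9"))) return(100)
    if (all(c(a, b) %in% c("Pop11", "Pop12"))) return(375)
    return(1000)
  }
  two3 <- c(a %in% c("Pop2", "Pop3"), b %in% c("Pop2", "Pop3"))
  if (all(two3)) return(500)
  if (any(two3)) return(1800)
  if (a == "Pop4" || b == "Pop4") return(1700)
  if (all(c(a, b) %in% c("Pop5", "Pop5b"))) return(20)
  if (all(c(a, b) %in% c("Pop5", "Pop5b", "Pop6"))) return(700)
  1000
}

# Subset painting profiles to given recipient groups, preserving attributes.
profiles_subset <- function(prof, groups) {
  s2 <- prof[prof$recipient_group %in% groups, ]
  attributes(s2) <- c(attributes(s2),
                      attributes(prof)[c("chrom_info", "donor_groups",
                                         "params", "level")])
  class(s2) <- class(prof)
  s2
}

# Admixture-dating fixture: two diverged source populations, 60/40 mosaics
# 50 generations old, painted and path-sampled for coancestry curves.
dating_fixture <- function(seed) {
  cache_fixture(paste0("dating_", seed), function() {
    p <- simulate_panel(two_pop_model(ne = 5000, split_gens = 2000),
                        c(A = 12, B = 12), regions = rep(4e7, 3),
                        mutation_rate = 5e-9, seed = seed)
    srcA <- panel_subset(p, individuals = paste0("A_", 1:6))
    srcB <- panel_subset(p, individuals = paste0("B_", 1:6))
    mos <- simulate_admixed_mosaic(srcA, srcB, proportion_source1 = 0.6,
                                   gens = 50, n_haploids = 20,
                                   seed = seed + 1)
    donors <- panel_subset(p, individuals = c(paste0("A_", 7:12),
                                              paste0("B_", 7:12)))
    comb <- haplotype_panel(
      rbind(mos$panel$haps, donors$haps), p$sites,
      dplyr::bind_rows(
        mos$panel$samples,
        dplyr::mutate(donors$samples,
                      hap1 = hap1 + nrow(mos$panel$haps),
                      hap2 = hap2 + nrow(mos$panel$haps))))
    list(panel = comb, mosaic = mos, src_groups = c("A", "B"))
  })
}
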