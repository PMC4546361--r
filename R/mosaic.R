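#' Simulate admixed haploid mosaics with known local-ancestry truth
#'
#' Builds haploid genomes as concatenations of stretches copied from two
#' source panels: stretch lengths in cM are i.i.d. Exponential with rate
#' `gens / 100` per cM (the expected ancestry-segment length `gens`
#' generations after a single admixture pulse), and each stretch comes from
#' a random haploid of source 1 with probability `proportion_source1`,
#' otherwise source 2.
#'
#' @param source1,source2 Two [haplotype_panel()]s sharing an identical
#'   site set.
#' @param proportion_source1 Probability in `[0, 1]` that a stretch is
#'   drawn from `source1`.
#' @param gens Generations since the admixture pulse (exponential rate is
#'   `gens/100` per cM).
#' @param n_haploids Number of mosaic haploids to simulate.
#' @param seed Integer seed.
#' @return A list with `panel` (a [haplotype_panel()] of
#'   `ceiling(n_haploids/2)` individuals labelled `admixed`) and `truth`
#'   (tibble: `haploid`, `chrom`, `start_cm`, `end_cm`, `source`), whose
#'   intervals tile each chromosome without overlap.
#' @export
simulate_admixed_mosaic <- function(source1, source2, proportion_source1,
                                    gens, n_haploids, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (proportion_source1 < 0 || proportion_source1 > 1)
    abort("`proportion_source1` must lie in [0, 1]")
  if (!isTRUE(all.equal(source1$sites$pos, source2$sites$pos)) ||
      !identical(source1$sites$chrom, source2$sites$chrom))
    abort("source panels must share an identical site set")

  set.seed(as.integer(seed))
  sites <- source1$sites
  chroms <- unique(sites$chrom)
  rate <- gens / 100           # per cM
  n_sites <- nrow(sites)
  haps <- matrix(0L, nrow = n_haploids, ncol = n_sites)
  truth <- vector("list", n_haploids)

  for (h in seq_len(n_haploids)) {
    iv <- list()
    for (ch in chroms) {
      idx <- which(sites$chrom == ch)
      cm <- sites$cm[idx]
      lo <- min(cm); hi <- max(cm)
      pos_cm <- lo
      repeat {
        g <- rexp(1, rate = rate)
        end_cm <- min(pos_cm + g, hi)
        src <- if (runif(1) < proportion_source1) 1L else 2L
        panel <- if (src == 1L) source1 else source2
        donor <- sample(nrow(panel$haps), 1)
        cover <- idx[cm >= pos_cm & (cm < end_cm | (end_cm >= hi & cm <= hi))]
        if (length(cover))
          haps[h, cover] <- panel$haps[donor, cover]
        iv[[length(iv) + 1]] <- list(chrom = ch, start_cm = pos_cm,
                                     end_cm = end_cm, source = src)
        pos_cm <- end_cm
        if (pos_cm >= hi) break
      }
    }
    truth[[h]] <- purrr::map_dfr(iv, as_tibble) %>%
      mutate(haploid = h, .before = 1)
  }

  n_ind <- ceiling(n_haploids / 2)
  pad <- 2L * n_ind - n_haploids
  if (pad > 0) {        # duplicate the last haploid to complete a diploid
    haps <- rbind(haps, haps[n_haploids, , drop = FALSE])
  }
  samples <- tibble(id = paste0("admixed_", seq_len(n_ind)),
                    group = "admixed",
                    hap1 = seq(1L, by = 2L, length.out = n_ind),
                    hap2 = seq(2L, by = 2L, length.out = n_ind))
  list(panel = haplotype_panel(haps, sites, samples),
       truth = bind_rows(truth) %>%
         mutate(source = paste0("source", .data$source)))
}

#' Fraction of truth genome (in cM) assigned to each source
#' @param truth Truth tibble from [simulate_admixed_mosaic()].
#' @return Tibble with `source` and `fraction`.
#' @export
truth_source_fractions <- function(truth) {
  truth %>%
    mutate(len = .data$end_cm - .data$start_cm) %>%
    group_by(.data$source) %>%
    summarise(cm = sum(.data$len), .groups = "drop") %>%
    mutate(fraction = .data$cm / sum(.data$cm))
}
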