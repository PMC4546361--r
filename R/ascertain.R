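#' Ascertain SNPs to a target minor-allele-frequency spectrum
#'
#' Mimics SNP-array ascertainment: within each region (chromosome) exactly
#' `n_per_region` sites are retained, allocated across 100 equally spaced
#' folded-MAF bins on `[0, 0.5]` in proportion to `target_spectrum`. Bins
#' with too few candidate sites leave a deficit that is filled by sites
#' drawn at random from the remainder.
#'
#' @param panel A [haplotype_panel()].
#' @param target_spectrum Numeric vector of length 100: desired bin masses
#'   (any non-negative weights; normalised internally). Defaults to the
#'   panel's own pooled spectrum, i.e. unbiased thinning.
#' @param n_per_region Number of SNPs to retain in each region.
#' @param seed Integer seed.
#' @return A [haplotype_panel()] with monomorphic sites removed and exactly
#'   `n_per_region` sites per region.
#' @export
ascertain_snps <- function(panel, target_spectrum = NULL, n_per_region, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (is.null(target_spectrum)) target_spectrum <- maf_spectrum(panel)
  target_spectrum <- as.numeric(target_spectrum)
  if (length(target_spectrum) != 100 || all(target_spectrum == 0) ||
      any(target_spectrum < 0))
    abort("`target_spectrum` must be 100 non-negative bin masses, not all zero")

  p <- colMeans(panel$haps)
  poly <- p > 0 & p < 1
  maf <- pmin(p, 1 - p)
  bin <- pmin(findInterval(maf, seq(0, 0.5, by = 0.005)), 100L)
  chroms <- unique(panel$sites$chrom)
  prob <- target_spectrum / sum(target_spectrum)

  set.seed(as.integer(seed))
  keep <- integer(0)
  for (ch in chroms) {
    idx <- which(panel$sites$chrom == ch & poly)
    if (length(idx) < n_per_region)
      abort(sprintf("region %s has only %d polymorphic sites (< n_per_region = %d)",
                    ch, length(idx), n_per_region))
    # integer bin quota via largest remainders
    quota <- floor(prob * n_per_region)
    rem <- prob * n_per_region - quota
    short <- n_per_region - sum(quota)
    if (short > 0)
      quota[order(rem, decreasing = TRUE)[seq_len(short)]] <-
        quota[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
    chosen <- integer(0)
    for (b in which(quota > 0)) {
      cand <- idx[bin[idx] == b]
      take <- min(length(cand), quota[b])
      if (take > 0)
        chosen <- c(chosen, if (length(cand) == 1) cand
                    else sample(cand, take))
    }
    deficit <- n_per_region - length(chosen)
    if (deficit > 0) {
      pool <- setdiff(idx, chosen)
      chosen <- c(chosen, if (length(pool) == 1) pool
                  else sample(pool, deficit))
    }
    keep <- c(keep, sort(chosen))
  }
  panel_subset(panel, sites = keep)
}
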