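#' Two-source local-ancestry posteriors via per-chromosome E-M
#'
#' Paints one recipient haploid using only the two surrogate groups as
#' donors, jointly re-estimating the switch rate, emission rate and
#' per-group copying prior within each chromosome by E-M, and returns the
#' final per-SNP posterior probability of copying from each group.
#'
#' @param panel A [haplotype_panel()].
#' @param haploid Recipient haploid row index.
#' @param surrogate_groups Two donor-group labels.
#' @param n_em E-M iterations per chromosome (default 50).
#' @param params Starting [copy_model_params()] (default:
#'   [default_switch_rate()] of the surrogate haploid count).
#' @return A tibble of class `source_posterior` with columns `haploid`,
#'   `chrom`, `site` and one probability column per surrogate group
#'   (summing to 1 per SNP); attribute `method = "EM"`.
#' @export
persite_posteriors_em <- function(panel, haploid, surrogate_groups,
                                  n_em = 50, params = NULL) {
  if (length(surrogate_groups) != 2) abort("exactly two surrogate groups")
  rows <- group_hap_rows(panel, surrogate_groups)
  id <- panel$samples$id[panel$samples$hap1 == haploid |
                           panel$samples$hap2 == haploid]
  if (length(id)) {
    s <- panel$samples[panel$samples$id == id, ]
    rows <- setdiff(rows, c(s$hap1, s$hap2))
  }
  if (length(rows) == 0) abort("empty donor set")
  p0 <- params %||% em_start_params(panel, length(rows))

  out <- list()
  for (ch in unique(panel$sites$chrom)) {
    em <- em_one_series(panel, haploid, rows, ch, p0, n_em,
                        est_switch = TRUE, est_emission = TRUE,
                        est_prior = TRUE)
    fit <- paint_haploid(panel, haploid, rows,
                         copy_model_params(em$switch_rate, em$emission_rate),
                         prior_weights = em$prior_weights,
                         site_posterior = TRUE)
    out[[length(out) + 1]] <- fit$site_posterior %>%
      filter(.data$chrom == ch)
  }
  res <- bind_rows(out) %>% mutate(haploid = haploid, .before = 1)
  structure(res, class = c("source_posterior", class(tibble())),
            method = "EM", sources = sort(surrogate_groups))
}

#' Recalibrate copy posteriors into ancestry posteriors (Bayes rule)
#'
#' Converts raw "probability of copying from X" posteriors into
#' "probability the true ancestry is D" using the surrogate groups' own
#' copying behaviour (confusion) and the target group's genome-wide
#' ancestry proportions:
#' `Pr(D | copy X) = f_X^D beta_D / sum_j f_X^j beta_j`, then
#' `Pr(D at l) = sum_X Pr(D | copy X) Pr(copy X at l)`.
#'
#' @param raw A `source_posterior` from [persite_posteriors_em()] or a
#'   plain painting posterior over the two groups.
#' @param confusion 2 x 2 matrix `f[X, D]`: average fraction that group-D
#'   individuals copy from donor group X (rows = copied group X, columns =
#'   true group D; self-copying excluded when painting the surrogates).
#' @param betas Named length-2 vector of genome-wide ancestry proportions
#'   of the target group for the two sources.
#' @return A `source_posterior` tibble with the same shape as `raw`,
#'   probabilities recalibrated per SNP (summing to 1); attribute
#'   `method = "NNLS"`.
#' @export
persite_posteriors_nnls <- function(raw, confusion, betas) {
  src <- attr(raw, "sources") %||% names(betas)
  if (length(src) != 2) abort("two sources required")
  if (!setequal(rownames(confusion), src) ||
      !setequal(colnames(confusion), src) || !setequal(names(betas), src))
    abort("confusion and betas must be labelled by the two sources")
  confusion <- confusion[src, src]
  betas <- betas[src]
  # Pr(D | copy X), rows X, cols D
  w <- sweep(confusion, 2, betas, `*`)
  denom <- rowSums(w)
  if (any(denom == 0)) abort("zero denominator in the Bayes ratio")
  cond <- w / denom
  p_raw <- as.matrix(raw[, src])
  p_new <- p_raw %*% cond
  p_new <- p_new / rowSums(p_new)
  out <- raw
  out[, src] <- as_tibble(p_new)
  attr(out, "method") <- "NNLS"
  out
}

#' Call contiguous high-confidence ancestry segments
#'
#' Maximal runs of consecutive SNPs whose posterior for `source` is
#' strictly above `threshold`; runs with fewer than `min_snps` SNPs are
#' discarded. Segment coordinates are 0-based half-open SNP indices
#' within each chromosome.
#'
#' @param posteriors A `source_posterior` tibble.
#' @param source Source label to call.
#' @param threshold Posterior threshold in `(0.5, 1)` (strictly greater
#'   comparison; ties excluded).
#' @param min_snps Minimum run length in SNPs.
#' @return Tibble of class `segment_calls`: `haploid`, `chrom`,
#'   `start_idx`, `end_idx` (0-based half-open within chromosome),
#'   `source`, `n_snps`, `min_posterior`.
#' @export
call_segments <- function(posteriors, source, threshold = 0.94,
                          min_snps = 100) {
  if (threshold <= 0.5 || threshold >= 1)
    abort("`threshold` must lie in (0.5, 1)")
  if (min_snps < 1) abort("`min_snps` must be >= 1")
  if (!(source %in% names(posteriors))) abort("unknown source label")
  empty <- tibble(haploid = integer(), chrom = character(),
                  start_idx = integer(), end_idx = integer(),
                  source = character(), n_snps = integer(),
                  min_posterior = numeric())
  srclab <- source
  out <- posteriors %>%
    group_by(.data$haploid, .data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      ok <- d[[srclab]] > threshold
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      keep <- r$values & r$lengths >= min_snps
      if (!any(keep))
        return(empty[, c("start_idx", "end_idx", "source", "n_snps",
                         "min_posterior")])
      tibble(start_idx = starts[keep] - 1L, end_idx = as.integer(ends[keep]),
             source = srclab, n_snps = as.integer(r$lengths[keep]),
             min_posterior = purrr::map2_dbl(starts[keep], ends[keep],
                                             ~min(d[[srclab]][.x:.y])))
    }) %>%
    ungroup()
  if (nrow(out) == 0) out <- empty
  class(out) <- c("segment_calls", class(tibble()))
  out
}

#' Allele-match similarity between two individuals within called segments
#'
#' For all four pairings of one haploid from each individual, pools the
#' SNPs that fall inside same-source called segments on both haploids and
#' reports the fraction of matching alleles.
#'
#' @param panel A [haplotype_panel()].
#' @param segments A `segment_calls` tibble covering the haploids of both
#'   individuals (single source).
#' @param individual_a,individual_b Individual ids.
#' @param source Source label to compare within.
#' @return Tibble with `individual_a`, `individual_b`, `source`,
#'   `n_snps`, `phi` (proportion matching; `NA` when no SNPs overlap).
#' @export
pairwise_similarity <- function(panel, segments, individual_a, individual_b,
                                source) {
  seg <- segments[segments$source == source, ]
  sa <- panel$samples[panel$samples$id == individual_a, ]
  sb <- panel$samples[panel$samples$id == individual_b, ]
  if (nrow(sa) != 1 || nrow(sb) != 1) abort("unknown individual id")
  covered <- function(hap) {
    s <- seg[seg$haploid == hap, ]
    if (nrow(s) == 0) return(integer(0))
    unlist(purrr::pmap(list(s$chrom, s$start_idx, s$end_idx),
                       function(ch, a, b) {
                         idx <- which(panel$sites$chrom == ch)
                         idx[(a + 1):b]
                       }))
  }
  tot <- 0L; match_n <- 0L
  for (ha in c(sa$hap1, sa$hap2))
    for (hb in c(sb$hap1, sb$hap2)) {
      ov <- intersect(covered(ha), covered(hb))
      if (length(ov)) {
        tot <- tot + length(ov)
        match_n <- match_n + sum(panel$haps[ha, ov] == panel$haps[hb, ov])
      }
    }
  tibble(individual_a = individual_a, individual_b = individual_b,
         source = source, n_snps = tot,
         phi = if (tot > 0) match_n / tot else NA_real_)
}

#' Ratio of introgressed to ancestral segment similarity per pair
#'
#' Joins per-pair allele-match similarities for the introgressed source
#' `I` and the ancestral source `A` and forms the per-pair ratio
#' `phi_I / phi_A`, summarised per group. Under a bottleneck that
#' postdates the admixture both segment classes are equally homogenised
#' and the ratio distribution matches the comparison group's; a bottleneck
#' (or split) predating the admixture depresses it.
#'
#' @param similarities Tibble of [pairwise_similarity()] rows for both
#'   sources, plus a `group` column for the pair.
#' @param source_i,source_a The introgressed and ancestral source labels.
#' @return List with `pairs` (per-pair ratios) and `by_group` (median and
#'   inner-quantile summaries per group).
#' @export
introgression_ratio <- function(similarities, source_i, source_a) {
  wide <- similarities %>%
    select("individual_a", "individual_b", "group", "source", "phi") %>%
    tidyr::pivot_wider(names_from = "source", values_from = "phi")
  if (!all(c(source_i, source_a) %in% names(wide)))
    abort("similarities must cover both sources")
  if (any(wide[[source_a]] == 0, na.rm = TRUE))
    abort("ancestral similarity of zero: ratio undefined")
  pairs <- wide %>%
    mutate(ratio = .data[[source_i]] / .data[[source_a]])
  by_group <- pairs %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(),
              median_ratio = stats::median(.data$ratio, na.rm = TRUE),
              q025 = stats::quantile(.data$ratio, 0.025, na.rm = TRUE,
                                     names = FALSE),
              q975 = stats::quantile(.data$ratio, 0.975, na.rm = TRUE,
                                     names = FALSE),
              .groups = "drop")
  list(pairs = pairs, by_group = by_group)
}

#' Per-SNP assignment accuracy of called segments against truth
#'
#' For every SNP inside a called segment, compares the call with the true
#' local-ancestry label at that SNP's cM position and reports the
#' proportion correct per segment-length bin (binned by the segment's
#' contiguous SNP count).
#'
#' @param segments A `segment_calls` tibble.
#' @param truth Truth tibble from [simulate_admixed_mosaic()].
#' @param panel The painted [haplotype_panel()] (for site cM positions).
#' @param length_bins Breaks for segment SNP-count bins.
#' @return Tibble with `bin`, `n_snps`, `accuracy`.
#' @export
assignment_accuracy <- function(segments, truth, panel,
                                length_bins = c(0, 50, 100, 200, 500, Inf)) {
  if (nrow(truth) == 0) abort("empty truth")
  per_snp <- segments %>%
    mutate(seg_id = dplyr::row_number()) %>%
    purrr::pmap_dfr(function(haploid, chrom, start_idx, end_idx, source,
                             n_snps, min_posterior, seg_id) {
      idx <- which(panel$sites$chrom == chrom)[(start_idx + 1):end_idx]
      cm <- panel$sites$cm[idx]
      tr <- truth[truth$haploid == haploid & truth$chrom == chrom, ]
      true_src <- vapply(cm, function(x) {
        hit <- which(tr$start_cm <= x & (x < tr$end_cm |
                                           x == max(tr$end_cm)))
        tr$source[hit[length(hit)]]
      }, character(1))
      tibble(n_snps = n_snps, correct = true_src == source)
    })
  per_snp %>%
    mutate(bin = cut(.data$n_snps, breaks = length_bins,
                     include.lowest = TRUE)) %>%
    group_by(.data$bin) %>%
    summarise(n_snps = dplyr::n(), accuracy = mean(.data$correct),
              .groups = "drop")
}
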