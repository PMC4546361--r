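#' Estimate copying-model parameters by expectation-maximisation
#'
#' Runs the E-M algorithm for the switch and/or emission rate separately
#' for every (recipient haploid, chromosome), then combines the estimates:
#' within each recipient the per-chromosome estimates are averaged weighted
#' by SNP count, and the per-recipient values are then averaged unweighted
#' across recipients. The observed-data log-likelihood is non-decreasing
#' over iterations for every series.
#'
#' @param panel A [haplotype_panel()].
#' @param donors A [donor_set()].
#' @param recipients Individual ids (default: all).
#' @param n_iterations Number of E-M steps (>= 1).
#' @param estimate_switch,estimate_emission Which parameters to update.
#' @param params Starting [copy_model_params()]; default uses
#'   [default_switch_rate()] for the donor-panel size.
#' @return A [copy_model_params()] with attributes `by_recipient` (tibble
#'   of per-recipient weighted estimates) and `loglik_trace` (tibble of
#'   per-iteration log-likelihoods per series).
#' @export
fit_copy_model_em <- function(panel, donors = donor_set("all_donors"),
                              recipients = NULL, n_iterations = 10,
                              estimate_switch = TRUE,
                              estimate_emission = TRUE,
                              params = NULL) {
  if (n_iterations < 1) abort("`n_iterations` must be >= 1")
  recipients <- recipients %||% panel$samples$id
  poly <- colMeans(panel$haps)
  if (all(poly == 0 | poly == 1)) abort("degenerate panel: all sites monomorphic")
  ci <- chrom_info(panel)
  rows_per <- lapply(recipients, function(id)
    resolve_donor_rows(panel, donors, recipient_id = id))

  est <- list(); trace <- list()
  for (i in seq_along(recipients)) {
    id <- recipients[i]
    rows <- rows_per[[i]]
    p0 <- params %||% em_start_params(panel, length(rows))
    s <- panel$samples[panel$samples$id == id, ]
    for (hap in c(s$hap1, s$hap2)) {
      for (ch in ci$chrom) {
        r <- em_one_series(panel, hap, rows, ch, p0, n_iterations,
                           estimate_switch, estimate_emission)
        est[[length(est) + 1]] <- tibble(
          recipient = id, haploid = hap, chrom = ch,
          n_snps = ci$n_snps[ci$chrom == ch],
          switch_rate = r$switch_rate, emission_rate = r$emission_rate)
        trace[[length(trace) + 1]] <- tibble(
          recipient = id, haploid = hap, chrom = ch,
          iteration = seq_along(r$loglik), loglik = r$loglik)
      }
    }
  }
  est <- bind_rows(est)
  by_rec <- est %>%
    group_by(.data$recipient) %>%
    summarise(switch_rate = weighted.mean(.data$switch_rate, .data$n_snps),
              emission_rate = weighted.mean(.data$emission_rate, .data$n_snps),
              .groups = "drop")
  out <- copy_model_params(mean(by_rec$switch_rate),
                           mean(by_rec$emission_rate))
  attr(out, "by_recipient") <- by_rec
  attr(out, "loglik_trace") <- bind_rows(trace)
  out
}

# E-M starting point: the 400000/H rule capped so the starting switch
# probability between typical adjacent sites stays below one half --
# at saturation (probability ~1 per interval) the switch posterior is
# uninformative and E-M cannot move.
em_start_params <- function(panel, n_donor_haploids) {
  md <- mean(unlist(lapply(split(panel$sites$cm, panel$sites$chrom),
                           site_gaps_morgan)))
  copy_model_params(min(default_switch_rate(n_donor_haploids),
                        log(2) / max(md, 1e-12)))
}

em_one_series <- function(panel, haploid, donor_rows, chrom, params, n_iter,
                          est_switch, est_emission, est_prior = FALSE,
                          prior_weights = NULL) {
  idx <- which(panel$sites$chrom == chrom)
  cm <- panel$sites$cm[idx]
  d <- site_gaps_morgan(cm)
  w <- site_weights_cm(cm)
  donors <- panel$haps[donor_rows, idx, drop = FALSE]
  rec <- panel$haps[haploid, idx]
  grp <- hap_group(panel)[donor_rows]
  donor_groups <- sort(unique(grp))
  g0 <- match(grp, donor_groups) - 1L
  L <- length(idx)

  sw <- params$switch_rate
  th <- params$emission_rate
  pw <- prior_weights %||% setNames(rep(1, length(donor_groups)), donor_groups)
  ll <- numeric(0)
  res <- NULL
  for (it in seq_len(n_iter)) {
    prior <- donor_prior(grp, donor_groups, if (est_prior) pw else NULL)
    res <- cp_hmm_cpp(donors, rec, d, sw, th, prior, g0,
                      length(donor_groups), w, FALSE, 0L)
    ll <- c(ll, res$loglik)
    if (est_switch && L > 1) sw <- mstep_switch(res$exp_switch, d, sw)
    if (est_emission) th <- min(max(res$exp_mismatch / L, 1e-9), 0.499)
    if (est_prior) {
      f <- as.numeric(res$f_cm)
      pw <- setNames(pmax(f / sum(f), 1e-9), donor_groups)
    }
  }
  list(switch_rate = sw, emission_rate = th, prior_weights = pw,
       loglik = ll, last = res,
       donor_groups = donor_groups, sites = idx)
}

# Exact M-step for the switch rate: maximise
#   sum_l J_l log(1 - exp(-n d_l)) - (1 - J_l) n d_l
# with J_l the posterior expected recombination indicator per interval.
mstep_switch <- function(J, d, current) {
  J <- pmin(pmax(J, 0), 1)
  q <- function(ln) {
    n <- exp(ln)
    p <- -expm1(-n * d)
    p <- pmax(p, 1e-300)
    sum(J * log(p) - (1 - J) * n * d)
  }
  opt <- optimize(q, interval = log(c(1e-2, 1e7)), maximum = TRUE)
  exp(opt$maximum)
}
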