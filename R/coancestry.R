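#' Build coancestry curves from sampled copy-paths
#'
#' For designated pairs of sampled copy-paths, every same-chromosome chunk
#' pair contributes the product of the two chunk sizes in cM (sizes capped
#' at `size_cap_cm`) to the 0.1 cM bin of the genetic distance between the
#' two chunks' midpoints, credited to the pair of donor groups involved.
#' With `S` surrogate groups this yields `choose(S, 2) + S` curves. The
#' decay rate of these curves with distance carries the time of any
#' admixture pulse.
#'
#' @param chunks Chunk tibble with columns `path` (integer path id),
#'   `chrom`, `mid_cm`, `size_cm`, `donor_group` (see
#'   [coancestry_chunks()]).
#' @param pairs Two-column matrix of path-id pairs to compare; defaults to
#'   all unordered pairs of distinct paths.
#' @param bin_cm,max_cm Bin width and maximum midpoint separation
#'   (centres at `bin_cm, 2 bin_cm, ..., max_cm`).
#' @param size_cap_cm Chunk sizes above this are capped (default 1 cM).
#' @param betas Optional named ancestry coefficients: surrogates with
#'   values below 0.001 are dropped and each curve's contents are
#'   reweighted by `1 / (beta_s1 * beta_s2)`.
#' The curve value is the observed/expected ratio per bin: the summed
#' product weight of ordered chunk pairs painted `(s1, s2)` divided by the
#' bin total times the product of the two groups' marginal weight shares
#' in that bin. The ratio hovers at 1 in the absence of ancestry linkage
#' and decays to 1 at the exponential rate set by the admixture time; it
#' cancels the chunk-size geometry that conditioning on a chunk pair at a
#' given midpoint separation would otherwise impose.
#'
#' @return Tibble of class `coancestry_curves`: `s1`, `s2`, `bin_cm`,
#'   `weight` (summed capped ordered products), `count` (chunk pairs),
#'   `total` (bin total over all group pairs), `value` (the ratio, `NA`
#'   for empty bins).
#' @export
build_curves <- function(chunks, pairs = NULL, bin_cm = 0.1, max_cm = 50,
                         size_cap_cm = 1, betas = NULL) {
  if (nrow(chunks) == 0) abort("empty paths")
  groups <- sort(unique(chunks$donor_group))
  if (!is.null(betas)) {
    keep <- names(betas)[betas >= 0.001]
    groups <- intersect(groups, keep)
    chunks <- chunks[chunks$donor_group %in% groups, ]
    if (nrow(chunks) == 0) abort("no chunks left after surrogate filtering")
  }
  path_ids <- sort(unique(chunks$path))
  if (is.null(pairs)) {
    if (length(path_ids) < 2) abort("need at least two paths")
    pairs <- t(utils::combn(path_ids, 2))
  }
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  chrom_id <- match(chunks$chrom, unique(chunks$chrom))
  res <- accumulate_curves_cpp(
    as.integer(chunks$path), chrom_id, chunks$mid_cm,
    pmin(chunks$size_cm, size_cap_cm),
    match(chunks$donor_group, groups), length(groups),
    pairs, bin_cm, max_cm)
  nbin <- dim(res$weight)[3]
  centers <- bin_cm * seq_len(nbin)
  S <- length(groups)
  # ordered-pair weights: each unordered same-group chunk pair represents
  # two ordered pairs
  O <- res$weight
  Cnt <- res$count
  for (i in seq_len(S)) {
    O[i, i, ] <- 2 * O[i, i, ]
    Cnt[i, i, ] <- 2 * Cnt[i, i, ]
  }
  if (!is.null(betas)) {
    b <- betas[groups]
    for (i in seq_len(S))
      for (j in seq_len(S))
        O[i, j, ] <- O[i, j, ] / (b[i] * b[j])
  }
  total <- apply(O, 3, sum)                    # per-bin grand total
  marg <- apply(O, c(1, 3), sum)               # S x nbin marginals
  out <- purrr::map_dfr(seq_len(S), function(i)
    purrr::map_dfr(seq(i, S), function(j) {
      ratio <- ifelse(total > 0 & marg[i, ] > 0 & marg[j, ] > 0,
                      (O[i, j, ] * total) / (marg[i, ] * marg[j, ]),
                      NA_real_)
      tibble(s1 = groups[i], s2 = groups[j], bin_cm = centers,
             weight = O[i, j, ], count = Cnt[i, j, ],
             total = total, value = ratio)
    }))
  class(out) <- c("coancestry_curves", class(out))
  out
}

#' Sample copy-paths for a set of individuals and tabulate their chunks
#'
#' Draws `n_samples` posterior copy-paths per haploid for each individual
#' and returns all chunks with globally unique path ids, plus the
#' within-individual path pairings used for coancestry curves: every pair
#' of distinct sampled paths between and within the individual's two
#' haploids (same-path self-pairings excluded).
#'
#' @param panel A [haplotype_panel()].
#' @param individuals Individual ids to sample.
#' @param donors A [donor_set()].
#' @param params A [copy_model_params()].
#' @param n_samples Paths per haploid (default 10).
#' @param seed Integer seed.
#' @return List with `chunks` (tibble including `path`) and `pairs`
#'   (two-column matrix of path ids).
#' @export
coancestry_chunks <- function(panel, individuals, donors, params,
                              n_samples = 10, seed) {
  if (missing(seed)) abort("`seed` is required")
  chunk_list <- list(); pair_list <- list()
  next_id <- 0L
  for (i in seq_along(individuals)) {
    s <- panel$samples[panel$samples$id == individuals[i], ]
    ids <- list()
    for (hap in c(s$hap1, s$hap2)) {
      sp <- sample_paintings(panel, hap, donors, params, n_samples,
                             seed = as.integer(seed) + next_id)
      ch <- sp$chunks %>%
        mutate(path = next_id + .data$sample,
               individual = individuals[i], haploid = hap)
      chunk_list[[length(chunk_list) + 1]] <- ch
      ids[[length(ids) + 1]] <- next_id + seq_len(n_samples)
      next_id <- next_id + n_samples
    }
    all_ids <- unlist(ids)
    pair_list[[i]] <- t(utils::combn(all_ids, 2))
  }
  list(chunks = bind_rows(chunk_list), pairs = do.call(rbind, pair_list))
}

#' Fit exponential admixture-date decay to coancestry curves
#'
#' Jointly fits `value ~ a_p + sum_q b_pq exp(-t_q * g / 100)` across all
#' curves `p` (bins weighted by chunk-pair counts), sharing the rate(s)
#' `t_q` -- the admixture date(s) in generations -- across curves while
#' profiling out per-curve intercepts and amplitudes by weighted least
#' squares. Bins below `min_cm` are excluded (short-range bins are
#' painting-noise dominated).
#'
#' @param curves A [build_curves()] result.
#' @param n_pulses 1 or 2 admixture pulses.
#' @param min_cm,max_cm Distance range used for fitting.
#' @param t_range Search range for dates, in generations.
#' @return An object of class `admixture_date_fit`: list with `dates`
#'   (tibble: `pulse`, `generations`, `year`, `year_label`), `amplitudes`
#'   (per curve and pulse), `rss`, `null_rss`, `r_squared_gain` and
#'   `no_signal` (TRUE when the exponential explains almost nothing
#'   beyond a constant).
#' @export
fit_admixture_date <- function(curves, n_pulses = 1, min_cm = 1,
                               max_cm = 50, t_range = c(1, 500)) {
  if (!n_pulses %in% 1:2) abort("`n_pulses` must be 1 or 2")
  d <- curves %>%
    filter(.data$bin_cm >= min_cm, .data$bin_cm <= max_cm,
           .data$count > 0, is.finite(.data$value)) %>%
    mutate(pair = paste(.data$s1, .data$s2, sep = ";"))
  if (nrow(d) == 0) abort("no usable bins in the fitting range")

  rss_for <- function(tt) {
    total <- 0
    coefs <- list()
    for (p in unique(d$pair)) {
      dp <- d[d$pair == p, ]
      X <- cbind(1, sapply(tt, function(t) exp(-t * dp$bin_cm / 100)))
      fit <- stats::lm.wfit(X, dp$value, dp$count)
      total <- total + sum(dp$count * fit$residuals^2)
      coefs[[p]] <- fit$coefficients
    }
    list(rss = total, coefs = coefs)
  }
  null_rss <- sum(purrr::map_dbl(unique(d$pair), function(p) {
    dp <- d[d$pair == p, ]
    mu <- weighted.mean(dp$value, dp$count)
    sum(dp$count * (dp$value - mu)^2)
  }))

  lt <- log(t_range)
  if (n_pulses == 1) {
    opt <- optimize(function(l) rss_for(exp(l))$rss, interval = lt)
    tt <- exp(opt$minimum)
  } else {
    starts <- list(log(c(10, 100)), log(c(30, 200)), log(c(5, 50)))
    best <- NULL
    for (s0 in starts) {
      o <- optim(s0, function(l) {
        l <- pmin(pmax(l, lt[1]), lt[2])
        rss_for(exp(l))$rss
      }, method = "Nelder-Mead")
      if (is.null(best) || o$value < best$value) best <- o
    }
    tt <- sort(exp(pmin(pmax(best$par, lt[1]), lt[2])))
    if (abs(tt[1] - tt[2]) < 1e-6)
      warn("the two fitted rates coincide; the data support a single pulse")
  }
  final <- rss_for(tt)
  gain <- if (null_rss > 0) 1 - final$rss / null_rss else 0
  amp <- purrr::imap_dfr(final$coefs, function(co, p)
    tibble(pair = p, intercept = co[1],
           pulse = seq_len(n_pulses), amplitude = co[-1]))
  dates <- tibble(pulse = seq_len(n_pulses), generations = tt,
                  year = generations_to_years(tt),
                  year_label = year_label(generations_to_years(tt)))
  structure(list(dates = dates, amplitudes = amp, rss = final$rss,
                 null_rss = null_rss, r_squared_gain = gain,
                 no_signal = gain < 0.01, n_pulses = n_pulses),
            class = "admixture_date_fit")
}

#' @export
print.admixture_date_fit <- function(x, ...) {
  if (x$no_signal) cat("<admixture_date_fit> no admixture signal\n")
  else cat(sprintf("<admixture_date_fit> %s generation(s) [%s]\n",
                   paste(round(x$dates$generations, 1), collapse = ", "),
                   paste(x$dates$year_label, collapse = ", ")))
  invisible(x)
}

#' Convert admixture dates in generations to calendar years
#'
#' `y = 1950 - (g + 1) * 28`: generation time 28 years, anchored at 1950
#' with one generation added for the sampled individuals themselves.
#' Positive years are CE, negative BCE.
#'
#' @param g Generations before present (>= 0).
#' @return Signed calendar year (negative = BCE).
#' @examples
#' generations_to_years(52)   # 466 (CE)
#' generations_to_years(121)  # -1466 (1466 BCE)
#' @export
generations_to_years <- function(g) {
  if (any(g < 0)) abort("`g` must be >= 0")
  1950 - (g + 1) * 28
}

#' @rdname generations_to_years
#' @param y Signed calendar year.
#' @export
year_label <- function(y) {
  ifelse(y < 0, paste0(abs(round(y)), "BCE"), paste0(round(y), "CE"))
}
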