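#' Configuration for the Dirichlet-multinomial clustering sampler
#'
#' @param C Fixed number of clusters (>= 1).
#' @param delta Dirichlet concentration of the cluster emission prior;
#'   larger values pull the cluster emission vectors together and so
#'   discourage sub-group formation.
#' @param M Iterations per chain.
#' @param burn_in Discarded initial iterations (`< M`).
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param n_chains Independent chains pooled into the final sample set.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(C, delta = 100, M = 200000, burn_in = 100000,
                           thin = 1000, n_chains = 10) {
  if (C < 1) abort("C must be >= 1")
  if (delta <= 0) abort("delta must be > 0")
  if (burn_in >= M) abort("burn_in must be < M")
  structure(list(C = as.integer(C), delta = delta, M = as.integer(M),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_chains = as.integer(n_chains)),
            class = "cluster_config")
}

#' Cluster individuals by their copied-length vectors (Gibbs sampler)
#'
#' Dirichlet-multinomial mixture with a fixed number of clusters `C`:
#' cluster emission vectors get a symmetric `Dirichlet(delta)` prior,
#' assignments a uniform prior, and the copied cM lengths enter a
#' multinomial likelihood as real-valued counts. Sampling alternates a
#' conjugate Dirichlet draw of each cluster's emission vector (entries
#' clamped to `[1e-7, 1 - 1e-7]` and renormalised), a categorical draw of
#' each assignment, and a refill step that moves one random distinct
#' individual into each empty cluster. Post-burn-in samples from
#' `n_chains` independent chains are pooled.
#'
#' @param lengths Either a [paint_panel()] result (genome-wide copied cM
#'   per donor group is extracted per individual) or a numeric matrix
#'   (rows = individuals with rownames, columns = donor groups).
#' @param config A [cluster_config()].
#' @param seed Integer seed.
#' @param keep_gamma Also retain sampled emission vectors?
#' @return An object of class `cluster_fit`: list with `psi` (pooled
#'   sample-by-individual assignment matrix), `ids`, `config` and
#'   optionally `gamma`.
#' @export
run_gibbs <- function(lengths, config, seed, keep_gamma = FALSE) {
  if (missing(seed)) abort("`seed` is required")
  if (inherits(lengths, "painting_profiles")) {
    g <- genome_profiles(lengths)
    wide <- tidyr::pivot_wider(g, id_cols = "recipient",
                               names_from = "donor_group",
                               values_from = "cm", values_fill = 0)
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$recipient
    lengths <- m
  }
  lengths <- as.matrix(lengths)
  if (any(lengths < 0)) abort("copied lengths must be non-negative")
  if (any(rowSums(lengths) == 0)) abort("each individual needs nonzero lengths")
  psi <- list(); gam <- list()
  for (chain in seq_len(config$n_chains)) {
    set.seed(as.integer(seed) + chain - 1L)
    r <- gibbs_dirmult_cpp(lengths, config$C, config$delta, config$M,
                           config$burn_in, config$thin, keep_gamma)
    psi[[chain]] <- r$psi
    if (keep_gamma) gam[[chain]] <- r$gamma
  }
  out <- list(psi = do.call(rbind, psi),
              ids = rownames(lengths), config = config)
  if (keep_gamma) out$gamma <- do.call(rbind, gam)
  structure(out, class = "cluster_fit")
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("<cluster_fit> %d individuals, C = %d, %d pooled samples\n",
              length(x$ids), x$config$C, nrow(x$psi)))
  invisible(x)
}

#' Pairwise co-assignment (coincidence) matrix
#'
#' Proportion of retained samples in which each pair of individuals falls
#' in the same cluster; symmetric with unit diagonal and invariant to
#' cluster relabelling within samples.
#'
#' @param fit A [run_gibbs()] result, or a samples-by-individuals
#'   assignment matrix.
#' @return N x N numeric matrix with individual ids as dimnames.
#' @export
coincidence_matrix <- function(fit) {
  psi <- if (inherits(fit, "cluster_fit")) fit$psi else as.matrix(fit)
  if (nrow(psi) == 0) abort("no samples")
  n <- ncol(psi)
  m <- matrix(0, n, n)
  for (s in seq_len(nrow(psi))) {
    same <- outer(psi[s, ], psi[s, ], "==")
    m <- m + same
  }
  m <- m / nrow(psi)
  ids <- if (inherits(fit, "cluster_fit")) fit$ids else colnames(psi)
  dimnames(m) <- list(ids, ids)
  m
}

#' Proportion of samples separating two labelled groups exactly
#'
#' With `C = 2`, the fraction of retained samples whose partition equals
#' the two-group labelling exactly (up to swapping the two cluster
#' labels).
#'
#' @param fit A [run_gibbs()] result (fitted with `C = 2`).
#' @param labels Named vector mapping individual id to one of two labels.
#' @return Proportion in `[0, 1]`.
#' @export
label_separation_rate <- function(fit, labels) {
  psi <- if (inherits(fit, "cluster_fit")) fit$psi else as.matrix(fit)
  ids <- if (inherits(fit, "cluster_fit")) fit$ids else colnames(psi)
  lab <- labels[ids]
  if (anyNA(lab)) abort("labels missing for some individuals")
  u <- unique(lab)
  if (length(u) != 2) abort("exactly two labels required with C = 2")
  target <- as.integer(lab == u[1])
  hits <- apply(psi, 1, function(p) {
    p <- as.integer(p == p[1])
    all(p == target) || all(p == 1L - target)
  })
  mean(hits)
}
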