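# Independent oracles, kept deliberately naive: exhaustive enumeration and
# grid search, never sharing code with the implementation they check.

# Exhaustive path-sum oracle for the copying HMM on tiny instances.
hmm_oracle <- function(donors, rec, d_morgan, switch_rate, theta,
                       prior = rep(1 / nrow(donors), nrow(donors))) {
  H <- nrow(donors); L <- ncol(donors)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), L)))
  emis <- function(h, l) if (donors[h, l] == rec[l]) 1 - theta else theta
  pp <- apply(paths, 1, function(x) {
    p <- prior[x[1]] * emis(x[1], 1)
    if (L > 1) for (l in 2:L) {
      s <- 1 - exp(-switch_rate * d_morgan[l - 1])
      p <- p * ((1 - s) * (x[l] == x[l - 1]) + s * prior[x[l]]) * emis(x[l], l)
    }
    p
  })
  lik <- sum(pp)
  post <- vapply(seq_len(L), function(l)
    vapply(seq_len(H), function(h) sum(pp[paths[, l] == h]) / lik,
           numeric(1)), numeric(H))
  list(loglik = log(lik), post = t(post), paths = paths, pp = pp / lik)
}

# Constrained least-squares oracle on the simplex (grid search + local
# refinement) for 2-3 surrogate cleaning problems.
nnls_simplex_oracle <- function(A, b, step = 0.002) {
  S <- ncol(A)
  obj <- function(x) sum((A %*% x - b)^2)
  if (S == 2) {
    g <- seq(0, 1, by = step)
    vals <- vapply(g, function(a) obj(c(a, 1 - a)), numeric(1))
    a <- g[which.min(vals)]
    c(a, 1 - a)
  } else if (S == 3) {
    g <- seq(0, 1, by = step * 5)
    best <- NULL; bv <- Inf
    for (a in g) for (bb in seq(0, 1 - a, by = step * 5)) {
      v <- obj(c(a, bb, 1 - a - bb))
      if (v < bv) { bv <- v; best <- c(a, bb, 1 - a - bb) }
    }
    # refine
    g2 <- seq(-0.01, 0.01, by = step / 2)
    for (da in g2) for (db in g2) {
      x <- best + c(da, db, -da - db)
      if (all(x >= 0) && obj(x) < bv) { bv <- obj(x); best2 <- x }
    }
    if (exists("best2")) best2 else best
  } else stop("oracle supports 2-3 surrogates")
}

# Exhaustive P(X) oracle over unordered within-group pairs.
p_statistic_oracle <- function(f_matrix, groups, x_label, y_label) {
  ix <- which(groups == x_label); iy <- which(groups == y_label)
  f_hat <- 0; n <- 0
  for (j in ix) for (k in iy) { f_hat <- f_hat + f_matrix[j, k]; n <- n + 1 }
  f_hat <- f_hat / n
  count_ge <- function(idx) {
    tot <- 0; ge <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a == b) next
      tot <- tot + 1
      if (f_matrix[idx[a], idx[b]] >= f_hat) ge <- ge + 1
    }
    # ordered sum with 1/choose(n,2) normalisation, halved for symmetry
    ge / 2 / choose(length(idx), 2)
  }
  list(p_x = count_ge(ix), p_y = count_ge(iy), f_hat = f_hat)
}

# Linear-scan segment caller.
segment_oracle <- function(prob, threshold, min_snps) {
  out <- list(); run_start <- NA
  for (i in seq_along(prob)) {
    if (prob[i] > threshold) {
      if (is.na(run_start)) run_start <- i
    }
    if ((prob[i] <= threshold || i == length(prob)) && !is.na(run_start)) {
      run_end <- if (prob[i] > threshold) i else i - 1
      if (run_end - run_start + 1 >= min_snps)
        out[[length(out) + 1]] <- c(run_start - 1L, run_end)
      run_start <- NA
    }
  }
  out
}

# Brute-force coancestry-bin accumulation for one pair of chunk sets.
curve_pair_oracle <- function(ch1, ch2, bin_cm = 0.1, max_cm = 50,
                              cap = 1) {
  rows <- list()
  for (i in seq_len(nrow(ch1))) for (j in seq_len(nrow(ch2))) {
    if (ch1$chrom[i] != ch2$chrom[j]) next
    d <- abs(ch1$mid_cm[i] - ch2$mid_cm[j])
    b <- round(d / bin_cm)
    if (b < 1 || b > max_cm / bin_cm) next
    rows[[length(rows) + 1]] <- data.frame(
      g1 = ch1$donor_group[i], g2 = ch2$donor_group[j], bin = b,
      w = min(ch1$size_cm[i], cap) * min(ch2$size_cm[j], cap))
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
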