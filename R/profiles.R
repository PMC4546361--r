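#' Remove self-copying from a copying vector
#'
#' Sets the vector's own-group entry to zero and rescales the remainder to
#' sum to one (the "(A-)" treatment of a painting profile).
#'
#' @param f Named copying vector over donor groups (sums to 1).
#' @param target_group The vector owner's group label.
#' @return Named copying vector with zero self-entry, summing to 1.
#' @export
remove_self_copy <- function(f, target_group) {
  if (!(target_group %in% names(f)))
    abort("target group absent from the donor axis")
  f[target_group] <- 0
  s <- sum(f)
  if (s <= 0) abort("copying vector is all-zero after removing self-copying")
  f / s
}

#' Clean a copying vector into ancestry proportions (constrained NNLS)
#'
#' Fits the target group's copying vector as a non-negative mixture of the
#' surrogate groups' copying vectors plus an optional self-copying term
#' whose design vector is zero except at the target's own entry. The
#' coefficients are constrained to be non-negative and to sum to one
#' (enforced by a heavily weighted auxiliary row in the least-squares
#' system); any coefficient at or below 0.001 is then set to zero and the
#' rest rescaled to sum to one.
#'
#' @param f_target Named copying vector of the target group (sums to 1).
#' @param donor_profiles Matrix of surrogate copying vectors: rows are
#'   surrogate groups (rownames), columns the donor-group axis matching
#'   `names(f_target)`.
#' @param target_group Label of the target group (used for the
#'   self-copying design vector); `NULL` disables self-copying.
#' @param self_copy Include the self-copying term (when the target's own
#'   entry on the donor axis is nonzero)?
#' @param threshold Coefficients at or below this are zeroed (default 0.001).
#' @param constraint_weight Weight of the sum-to-one row (default 1000;
#'   large enough that the constraint holds to ~1e-8 while keeping the
#'   augmented system well conditioned for the active-set solver; halved
#'   and retried on numerical failure).
#' @return An object of class `ancestry_profile`: a tibble (`surrogate`,
#'   `beta`) with attributes `beta_self`, `residual_norm` and `target`.
#' @export
clean_profile_nnls <- function(f_target, donor_profiles, target_group = NULL,
                               self_copy = TRUE, threshold = 0.001,
                               constraint_weight = 1000) {
  axis <- names(f_target)
  if (is.null(axis) || is.null(colnames(donor_profiles)) ||
      !setequal(axis, colnames(donor_profiles)))
    abort("target vector and surrogate profiles must share the donor axis")
  donor_profiles <- donor_profiles[, axis, drop = FALSE]
  surrogates <- rownames(donor_profiles)
  A <- t(donor_profiles)
  use_self <- isTRUE(self_copy) && !is.null(target_group) &&
    target_group %in% axis && f_target[target_group] > 0
  if (use_self) {
    self_col <- rep(0, length(axis))
    self_col[match(target_group, axis)] <- f_target[target_group]
    A <- cbind(A, SELF = self_col)
  }
  if (all(A == 0)) abort("all-zero design")
  wt <- constraint_weight
  x <- NULL
  for (try_w in wt * c(1, 0.5, 0.1, 0.01)) {
    x <- tryCatch(
      pracma::lsqnonneg(rbind(A, try_w * rep(1, ncol(A))),
                        c(as.numeric(f_target), try_w))$x,
      error = function(e) NULL)
    if (!is.null(x)) break
  }
  if (is.null(x)) abort("constrained non-negative fit failed")
  names(x) <- colnames(A)

  x[x <= threshold] <- 0
  if (sum(x) == 0) abort("all coefficients thresholded to zero")
  x <- x / sum(x)
  resid <- as.numeric(f_target) - as.numeric(A %*% x)
  beta_self <- if (use_self) unname(x["SELF"]) else 0
  beta <- x[setdiff(names(x), "SELF")]
  structure(tibble(surrogate = names(beta), beta = unname(beta)),
            class = c("ancestry_profile", class(tibble())),
            beta_self = beta_self,
            residual_norm = sqrt(sum(resid^2)),
            target = target_group)
}

#' Weighted block-jackknife standard errors
#'
#' Delete-one-block jackknife with unequal block sizes, combining the full
#' and leave-one-out estimates with the weighted variance formula of
#' Busing et al. (1999): with block weights \eqn{m_j}, \eqn{n = \sum m_j},
#' \eqn{h_j = n / m_j}, pseudovalues
#' \eqn{\tau_j = h_j \hat\theta - (h_j - 1)\hat\theta_{(j)}} and
#' \eqn{\theta_J = g\hat\theta - \sum_j (1 - m_j/n)\hat\theta_{(j)}}, the
#' variance is \eqn{g^{-1} \sum_j (\tau_j - \theta_J)^2 / (h_j - 1)}.
#' Only relative weights matter.
#'
#' @param full Numeric vector: estimate on all blocks.
#' @param deletes Matrix with one row per deleted block, columns matching
#'   `full`.
#' @param weights Positive block weights (e.g. per-chromosome SNP counts).
#' @return Standard-error vector, one per coefficient.
#' @export
jackknife_se <- function(full, deletes, weights) {
  deletes <- as.matrix(deletes)
  g <- nrow(deletes)
  if (g < 2) abort("jackknife needs at least two blocks")
  if (length(weights) != g) abort("one weight per block required")
  n <- sum(weights)
  h <- n / weights
  tau <- matrix(h, g, length(full)) * rep(full, each = g) - (h - 1) * deletes
  theta_j <- g * full - colSums((1 - weights / n) * deletes)
  dev2 <- (tau - rep(theta_j, each = g))^2 / (h - 1)
  sqrt(colSums(dev2) / g)
}

#' Ancestry proportions for a recipient group with jackknife uncertainty
#'
#' Builds the genome-wide copying vectors of the target and surrogate
#' groups from painting profiles, cleans the target with
#' [clean_profile_nnls()], and attaches weighted block-jackknife standard
#' errors from delete-one-chromosome re-fits (weights = chromosome SNP
#' counts).
#'
#' @param profiles A [paint_panel()] result (individual level; averaged
#'   internally) covering the target and surrogate groups as recipients.
#' @param target_group Recipient group to clean.
#' @param surrogates Candidate surrogate groups (default: all painted
#'   groups except the target).
#' @param self_copy Allow the self-copying term?
#' @return An `ancestry_profile` tibble (`surrogate`, `beta`, `se`) with
#'   attributes `beta_self`, `se_self`, `residual_norm`, `target`.
#' @export
ancestry_profile <- function(profiles, target_group, surrogates = NULL,
                             self_copy = TRUE) {
  grp <- aggregate_profiles(profiles)
  all_groups <- unique(grp$recipient_group)
  surrogates <- surrogates %||% setdiff(all_groups, target_group)
  if (!(target_group %in% all_groups)) abort("target group was not painted")
  ci <- attr(profiles, "chrom_info")

  fit_on <- function(chrom_drop = NULL) {
    tbl <- grp
    if (!is.null(chrom_drop)) tbl <- tbl[tbl$chrom != chrom_drop, ]
    wide <- tbl %>%
      group_by(.data$recipient_group, .data$donor_group) %>%
      summarise(cm = sum(.data$cm), .groups = "drop_last") %>%
      mutate(f = .data$cm / sum(.data$cm)) %>%
      ungroup() %>%
      tidyr::pivot_wider(id_cols = "recipient_group",
                         names_from = "donor_group", values_from = "f",
                         values_fill = 0)
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$recipient_group
    fit <- clean_profile_nnls(m[target_group, ],
                              m[surrogates, , drop = FALSE],
                              target_group = target_group,
                              self_copy = self_copy)
    list(coef = c(fit$beta, attr(fit, "beta_self")), fit = fit)
  }

  full <- fit_on()
  if (nrow(ci) < 2) {
    se <- rep(NA_real_, length(full$coef))
  } else {
    deletes <- t(vapply(ci$chrom, function(ch) fit_on(ch)$coef,
                        numeric(length(full$coef))))
    se <- jackknife_se(full$coef, deletes, ci$n_snps)
  }
  k <- nrow(full$fit)
  out <- full$fit %>% mutate(se = se[seq_len(k)])
  structure(out,
            class = c("ancestry_profile", class(tibble())),
            beta_self = attr(full$fit, "beta_self"),
            se_self = se[k + 1],
            residual_norm = attr(full$fit, "residual_norm"),
            target = target_group)
}

#' @export
print.ancestry_profile <- function(x, ...) {
  cat(sprintf("<ancestry_profile> target: %s, beta_self = %.4f, residual = %.4g\n",
              attr(x, "target") %||% "?", attr(x, "beta_self"),
              attr(x, "residual_norm")))
  NextMethod()
}
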