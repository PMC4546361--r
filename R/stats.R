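#' Total variation distance between two copying vectors
#'
#' `TVD = 0.5 * sum_k |f_k^X - f_k^Y|`: half the L1 distance between two
#' probability vectors over the shared donor-group axis.
#'
#' @param f_x,f_y Named copying vectors summing to 1 (tolerance 1e-6).
#' @return Value in `[0, 1]`.
#' @export
tvd <- function(f_x, f_y) {
  if (!is.null(names(f_x)) || !is.null(names(f_y))) {
    if (is.null(names(f_x)) || is.null(names(f_y)) ||
        !setequal(names(f_x), names(f_y)))
      abort("copying vectors must share the donor axis")
    f_y <- f_y[names(f_x)]
  } else if (length(f_x) != length(f_y)) {
    abort("copying vectors must share the donor axis")
  }
  if (abs(sum(f_x) - 1) > 1e-6 || abs(sum(f_y) - 1) > 1e-6)
    abort("copying vectors must sum to 1")
  0.5 * sum(abs(f_x - f_y))
}

#' Within-recipient, between-chromosome total variation distance
#'
#' The SNP-count-weighted mean over chromosomes of half the L1 distance
#' between each chromosome's copying vector and the genome-wide vector:
#' `0.5 * sum_i (L_i/L) * sum_k |f_ik - f_k|`. Measures how much
#' independent drift moves the recipient's ancestry profile from
#' chromosome to chromosome.
#'
#' @param per_chrom Matrix of per-chromosome copying vectors (rows =
#'   chromosomes, columns = donor groups).
#' @param genome Genome-wide copying vector (same column order).
#' @param weights Per-chromosome SNP counts `L_i`.
#' @return Non-negative value.
#' @export
tvd_within <- function(per_chrom, genome, weights) {
  per_chrom <- as.matrix(per_chrom)
  if (length(weights) != nrow(per_chrom))
    abort("one weight per chromosome required")
  if (ncol(per_chrom) != length(genome)) abort("donor axes differ")
  dev <- 0.5 * rowSums(abs(sweep(per_chrom, 2, genome)))
  sum(weights / sum(weights) * dev)
}

#' Drift-scaled profile distance between two recipients
#'
#' `F_XY = TVD_XY / (0.5 * (TVD~_X + TVD~_Y))`: the between-recipient
#' distance scaled by the mean within-recipient between-chromosome
#' distance, attenuating differences caused by drift alone. Undefined
#' (returned as `NA`) when both within values are zero.
#'
#' @param x,y Lists with elements `genome` (copying vector), `per_chrom`
#'   (chromosome x donor-group matrix) and `weights` (SNP counts).
#' @return Non-negative value, or `NA` when undefined.
#' @export
f_xy <- function(x, y) {
  t_xy <- tvd(x$genome, y$genome)
  t_x <- tvd_within(x$per_chrom, x$genome, x$weights)
  t_y <- tvd_within(y$per_chrom, y$genome, y$weights)
  denom <- 0.5 * (t_x + t_y)
  if (denom == 0) return(NA_real_)
  t_xy / denom
}

#' Extract per-recipient comparison inputs from painting profiles
#' @noRd
profile_inputs <- function(profiles, level = c("individual", "group")) {
  level <- match.arg(level)
  tbl <- if (level == "group") aggregate_profiles(profiles) else
    as_tibble(profiles)
  ci <- attr(profiles, "chrom_info")
  axis <- sort(unique(tbl$donor_group))
  split_tbl <- split(tbl, tbl$recipient)
  purrr::map(split_tbl, function(d) {
    wide <- tidyr::pivot_wider(d, id_cols = "chrom",
                               names_from = "donor_group",
                               values_from = "cm", values_fill = 0)
    wide <- wide[match(ci$chrom, wide$chrom), ]
    m <- as.matrix(wide[, axis, drop = FALSE])
    genome <- colSums(m) / sum(m)
    per_chrom <- m / rowSums(m)
    list(genome = genome, per_chrom = per_chrom, weights = ci$n_snps,
         group = d$recipient_group[1])
  })
}

#' All pairwise profile comparisons between recipients
#'
#' @param profiles A [paint_panel()] result.
#' @param level Compare `"group"`-average or `"individual"` profiles.
#' @return Tibble of class `profile_comparison` with `x`, `y`, `tvd`,
#'   `tvd_within_x`, `tvd_within_y`, `f_xy` for every unordered pair.
#' @export
compare_profiles <- function(profiles, level = c("group", "individual")) {
  level <- match.arg(level)
  inp <- profile_inputs(profiles, level)
  ids <- names(inp)
  pairs <- utils::combn(ids, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- inp[[pairs[1, i]]]; b <- inp[[pairs[2, i]]]
    tibble(x = pairs[1, i], y = pairs[2, i],
           x_group = a$group, y_group = b$group,
           tvd = tvd(a$genome, b$genome),
           tvd_within_x = tvd_within(a$per_chrom, a$genome, a$weights),
           tvd_within_y = tvd_within(b$per_chrom, b$genome, b$weights),
           f_xy = f_xy(a, b))
  })
  class(out) <- c("profile_comparison", class(out))
  out
}

#' Pairwise individual-level F matrix for two groups
#'
#' @param profiles A [paint_panel()] result covering both groups.
#' @param groups Two group labels.
#' @return Square matrix of `F_jk` over individuals of the two groups,
#'   with individual ids as dimnames and a `groups` attribute mapping
#'   individual to group.
#' @export
pairwise_f_matrix <- function(profiles, groups) {
  inp <- profile_inputs(profiles, "individual")
  inp <- inp[purrr::map_chr(inp, "group") %in% groups]
  ids <- names(inp)
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) {
      v <- f_xy(inp[[i]], inp[[j]])
      m[i, j] <- v; m[j, i] <- v
    }
  diag(m) <- 0
  attr(m, "groups") <- purrr::map_chr(inp, "group")
  m
}

#' Within-group exceedance proportion P(X)
#'
#' With `F_hat` the mean pairwise `F` over all between-group individual
#' pairs, `P(X)` is the proportion of within-X unordered pairs whose `F`
#' is at least `F_hat` (ties count as exceeding). Values near 0.5 indicate
#' no ancestry difference between the groups beyond drift; values near 0
#' indicate distinct ancestry.
#'
#' @param f_matrix Square pairwise-`F` matrix with a `groups` attribute
#'   (see [pairwise_f_matrix()]), or pass `groups` explicitly.
#' @param x_label,y_label The two group labels.
#' @param groups Optional per-individual group labels (row order).
#' @return Tibble with `p_x`, `p_y` and the between-group mean `f_hat`.
#' @export
p_statistic <- function(f_matrix, x_label, y_label, groups = NULL) {
  groups <- groups %||% attr(f_matrix, "groups")
  if (is.null(groups)) abort("per-individual group labels required")
  ix <- which(groups == x_label); iy <- which(groups == y_label)
  if (length(ix) < 2 || length(iy) < 2)
    abort("both groups need at least two individuals")
  f_hat <- mean(f_matrix[ix, iy])
  prop_ge <- function(idx) {
    v <- f_matrix[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
    mean(v >= f_hat)
  }
  tibble(x = x_label, y = y_label,
         p_x = prop_ge(ix), p_y = prop_ge(iy), f_hat = f_hat)
}

#' Hudson's F_ST between two populations of a panel
#'
#' Ratio-of-averages Hudson estimator: per site, numerator
#' `(p_a - p_b)^2 - p_a(1-p_a)/(n_a-1) - p_b(1-p_b)/(n_b-1)` and
#' denominator `p_a(1-p_b) + p_b(1-p_a)`, summed over sites before taking
#' the ratio. Sample-size robust and standard for calibrating simulated
#' differentiation.
#'
#' @param panel A [haplotype_panel()].
#' @param pop_a,pop_b Group labels.
#' @return F_ST estimate (can be slightly negative at low differentiation).
#' @export
hudson_fst <- function(panel, pop_a, pop_b) {
  ra <- group_hap_rows(panel, pop_a)
  rb <- group_hap_rows(panel, pop_b)
  if (length(ra) < 2 || length(rb) < 2)
    abort("need at least two haploids per population")
  pa <- colMeans(panel$haps[ra, , drop = FALSE])
  pb <- colMeans(panel$haps[rb, , drop = FALSE])
  poly <- (pa > 0 | pb > 0) & (pa < 1 | pb < 1)
  if (!any(poly)) abort("no polymorphic sites")
  na <- length(ra); nb <- length(rb)
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
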