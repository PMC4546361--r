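#' Tidy an ancestry profile
#'
#' @param x An [ancestry_profile()].
#' @param ... Unused.
#' @return Tibble with `surrogate`, `beta`, `se` (when available) plus a
#'   `SELF` row when self-copying was fitted.
#' @export
tidy.ancestry_profile <- function(x, ...) {
  out <- as_tibble(x)
  if ((attr(x, "beta_self") %||% 0) > 0)
    out <- bind_rows(out, tibble(surrogate = "SELF",
                                 beta = attr(x, "beta_self"),
                                 se = attr(x, "se_self") %||% NA_real_))
  out
}

#' @rdname tidy.ancestry_profile
#' @export
glance.ancestry_profile <- function(x, ...) {
  tibble(target = attr(x, "target") %||% NA_character_,
         n_surrogates = sum(x$beta > 0),
         beta_self = attr(x, "beta_self") %||% 0,
         residual_norm = attr(x, "residual_norm"))
}

#' Tidy an admixture-date fit
#'
#' @param x An [fit_admixture_date()] result.
#' @param ... Unused.
#' @return The per-pulse date tibble.
#' @export
tidy.admixture_date_fit <- function(x, ...) x$dates

#' @rdname tidy.admixture_date_fit
#' @export
glance.admixture_date_fit <- function(x, ...) {
  tibble(n_pulses = x$n_pulses, rss = x$rss, null_rss = x$null_rss,
         r_squared_gain = x$r_squared_gain, no_signal = x$no_signal)
}

#' Tidy a cluster fit into per-individual assignment summaries
#'
#' @param x A [run_gibbs()] result.
#' @param ... Unused.
#' @return Tibble with `id`, `modal_cluster`, `p_modal`.
#' @export
tidy.cluster_fit <- function(x, ...) {
  modal <- apply(x$psi, 2, function(col) {
    tb <- table(col)
    c(as.integer(names(tb)[which.max(tb)]), max(tb) / length(col))
  })
  tibble(id = x$ids, modal_cluster = as.integer(modal[1, ]),
         p_modal = modal[2, ])
}

#' @rdname tidy.cluster_fit
#' @export
glance.cluster_fit <- function(x, ...) {
  tibble(n_individuals = length(x$ids), C = x$config$C,
         delta = x$config$delta, n_samples = nrow(x$psi),
         n_chains = x$config$n_chains)
}
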