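#' Plot painting profiles as stacked copying-vector bars
#'
#' @param object A [paint_panel()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.painting_profiles <- function(object, ...) {
  g <- genome_profiles(object)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$recipient, y = .data$f,
                                  fill = .data$donor_group)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ recipient_group, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "copied fraction", fill = "donor group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot an ancestry profile with jackknife error bars
#'
#' @param object An [ancestry_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ancestry_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$surrogate, y = .data$beta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$beta - 2 * .data$se, 0),
                                        ymax = .data$beta + 2 * .data$se),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "surrogate group", y = "ancestry proportion",
                  title = paste("target:", attr(object, "target"))) +
    ggplot2::theme_minimal()
}

#' Plot coancestry curves with optional fitted decays
#'
#' @param object A [build_curves()] result.
#' @param fit Optional [fit_admixture_date()] result to overlay.
#' @param min_cm Lower distance bound shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coancestry_curves <- function(object, fit = NULL, min_cm = 1, ...) {
  d <- as_tibble(object) %>%
    filter(.data$bin_cm >= min_cm, !is.na(.data$value)) %>%
    mutate(pair = paste(.data$s1, .data$s2, sep = ";"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_cm, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "genetic distance (cM)", y = "mean chunk-size product") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- fit$dates$generations
    pred <- fit$amplitudes %>%
      group_by(.data$pair) %>%
      dplyr::reframe(bin_cm = unique(d$bin_cm),
                     value = .data$intercept[1] +
                       rowSums(sapply(seq_along(tt), function(q)
                         .data$amplitude[q] * exp(-tt[q] * unique(d$bin_cm) / 100))))
    p <- p + ggplot2::geom_line(data = pred, colour = "forestgreen")
  }
  p
}

#' Heatmap of a pairwise coincidence matrix
#'
#' @param m A [coincidence_matrix()] result.
#' @return A ggplot.
#' @export
plot_coincidence <- function(m) {
  d <- as_tibble(m, rownames = "a") %>%
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "p") %>%
    mutate(a = factor(.data$a, rownames(m)),
           b = factor(.data$b, rownames(m)))
  ggplot2::ggplot(d, ggplot2::aes(.data$a, .data$b, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-assignment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
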