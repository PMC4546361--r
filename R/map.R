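#' Build a genetic map
#'
#' @param chrom Chromosome label (recycled).
#' @param pos Base-pair positions, strictly increasing.
#' @param cm Cumulative centimorgans, non-decreasing, same length as `pos`.
#' @return A tibble of class `genetic_map` with columns `chrom`, `pos`, `cm`.
#' @export
genetic_map <- function(chrom, pos, cm) {
  if (length(pos) != length(cm)) abort("`pos` and `cm` must have equal length")
  out <- tibble(chrom = chrom, pos = as.integer(pos), cm = as.numeric(cm)) %>%
    arrange(match(.data$chrom, unique(.data$chrom)), .data$pos)
  ok <- out %>%
    group_by(.data$chrom) %>%
    summarise(ok = all(diff(.data$pos) > 0) && all(diff(.data$cm) >= 0),
              .groups = "drop")
  if (!all(ok$ok)) abort("positions must be strictly increasing and cM non-decreasing")
  class(out) <- c("genetic_map", class(out))
  out
}

#' Interpolate cM positions for sites from a genetic map
#'
#' Sites between map points are linearly interpolated; sites beyond the map
#' ends are extrapolated at the boundary recombination rate, with a warning.
#'
#' @param map A [genetic_map()].
#' @param chrom,pos Site coordinates.
#' @return Numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, chrom, pos) {
  if (length(chrom) == 1) chrom <- rep(chrom, length(pos))
  out <- numeric(length(pos))
  extrapolated <- FALSE
  for (ch in unique(chrom)) {
    m <- map[map$chrom == ch, ]
    if (nrow(m) == 0) abort(paste0("map has no points for chromosome ", ch))
    idx <- which(chrom == ch)
    p <- pos[idx]
    if (nrow(m) == 1) {
      out[idx] <- m$cm[1]
      next
    }
    cm <- approx(m$pos, m$cm, xout = p, rule = 1)$y
    # boundary-rate extrapolation
    lo <- p < m$pos[1]
    hi <- p > m$pos[nrow(m)]
    if (any(lo)) {
      r <- (m$cm[2] - m$cm[1]) / (m$pos[2] - m$pos[1])
      cm[lo] <- m$cm[1] - (m$pos[1] - p[lo]) * r
      extrapolated <- TRUE
    }
    if (any(hi)) {
      nm <- nrow(m)
      r <- (m$cm[nm] - m$cm[nm - 1]) / (m$pos[nm] - m$pos[nm - 1])
      cm[hi] <- m$cm[nm] + (p[hi] - m$pos[nm]) * r
      extrapolated <- TRUE
    }
    out[idx] <- cm
  }
  if (extrapolated)
    warn("some sites fall outside the genetic map; extrapolated at the boundary rate")
  out
}

#' Read / write a genetic map as 3-column tab-separated text
#'
#' Columns: chromosome, base-pair position, cumulative cM.
#' @param path File path.
#' @return [read_genetic_map()] returns a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  d <- readr::read_tsv(path, col_names = c("chrom", "pos", "cm"),
                       col_types = "cid", progress = FALSE)
  genetic_map(d$chrom, d$pos, d$cm)
}

#' @rdname read_genetic_map
#' @param map A [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(as_tibble(map)[, c("chrom", "pos", "cm")], path,
                   col_names = FALSE)
  invisible(path)
}
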