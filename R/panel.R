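#' Phased haplotype panel
#'
#' The central data container: a matrix of phased biallelic haplotypes with
#' per-site genetic-map positions and per-individual group labels. Every
#' painting, statistic and simulation stage consumes or produces one.
#'
#' @param haps Integer matrix over \{0, 1\}; rows are haploid genomes,
#'   columns are sites.
#' @param sites Data frame with one row per site: `chrom` (chromosome or
#'   region label), `pos` (base-pair position, strictly increasing within
#'   chromosome) and `cm` (cumulative centimorgans, non-decreasing within
#'   chromosome).
#' @param samples Data frame with one row per individual: `id`, `group`,
#'   and the two haploid row indices `hap1`, `hap2`.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haps, sites, samples) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  stopifnot(all(c("chrom", "pos", "cm") %in% names(sites)),
            all(c("id", "group", "hap1", "hap2") %in% names(samples)))
  if (nrow(sites) != ncol(haps))
    abort("`sites` must have one row per haplotype column")
  if (!all(haps %in% c(0L, 1L)))
    abort("haplotypes must be biallelic 0/1")
  idx <- c(samples$hap1, samples$hap2)
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > nrow(haps)))
    abort("each individual needs two distinct haploid rows within the matrix")
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    abort("sites must be sorted by (chromosome, position)")
  bad <- sites %>%
    group_by(.data$chrom) %>%
    summarise(ok = all(diff(.data$pos) > 0) && all(diff(.data$cm) >= 0),
              .groups = "drop")
  if (!all(bad$ok))
    abort("positions must be strictly increasing and cM non-decreasing")
  structure(list(haps = haps, sites = sites, samples = samples),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haploids / %d individuals, %d sites, %d chromosome(s), %d group(s)\n",
              nrow(x$haps), nrow(x$samples), nrow(x$sites),
              length(unique(x$sites$chrom)), length(unique(x$samples$group))))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$haps)

panel_groups <- function(panel) unique(panel$samples$group)

#' Haploid row indices belonging to a set of groups
#' @noRd
group_hap_rows <- function(panel, groups) {
  s <- panel$samples[panel$samples$group %in% groups, ]
  sort(c(s$hap1, s$hap2))
}

#' Subset a panel to chosen sites and/or individuals
#'
#' @param panel A [haplotype_panel()].
#' @param sites Integer site (column) indices to keep, in order.
#' @param individuals Individual ids to keep.
#' @return A [haplotype_panel()].
#' @export
panel_subset <- function(panel, sites = NULL, individuals = NULL) {
  haps <- panel$haps
  st <- panel$sites
  sm <- panel$samples
  if (!is.null(sites)) {
    haps <- haps[, sites, drop = FALSE]
    st <- st[sites, ]
  }
  if (!is.null(individuals)) {
    sm <- sm[sm$id %in% individuals, ]
    rows <- c(rbind(sm$hap1, sm$hap2))
    haps <- haps[rows, , drop = FALSE]
    sm$hap1 <- seq(1L, by = 2L, length.out = nrow(sm))
    sm$hap2 <- sm$hap1 + 1L
  }
  haplotype_panel(haps, st, sm)
}

#' Drop sites that are monomorphic across the panel
#' @param panel A [haplotype_panel()].
#' @return A [haplotype_panel()].
#' @export
drop_monomorphic <- function(panel) {
  p <- colMeans(panel$haps)
  panel_subset(panel, sites = which(p > 0 & p < 1))
}

#' Per-chromosome SNP counts and cM spans
#'
#' @param panel A [haplotype_panel()].
#' @return A tibble with `chrom`, `n_snps`, `cm_span`.
#' @export
chrom_info <- function(panel) {
  panel$sites %>%
    group_by(.data$chrom) %>%
    summarise(n_snps = dplyr::n(),
              cm_span = max(.data$cm) - min(.data$cm), .groups = "drop")
}

#' Folded minor-allele-frequency spectrum over 100 bins
#'
#' Bins are half-open `[x, x + 0.005)` covering `[0, 0.5]`; a frequency of
#' exactly 0.5 falls in the last bin.
#'
#' @param panel A [haplotype_panel()].
#' @return Integer vector of length 100 of site counts per bin.
#' @export
maf_spectrum <- function(panel) {
  p <- colMeans(panel$haps)
  maf <- pmin(p, 1 - p)
  bin <- pmin(findInterval(maf, seq(0, 0.5, by = 0.005)), 100L)
  tabulate(bin, nbins = 100L)
}
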