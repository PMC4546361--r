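#' Write a haplotype panel to disk
#'
#' Formats:
#' \describe{
#'   \item{`vcf`}{`<prefix>.vcf` with phased GT fields and contig headers,
#'     plus `<prefix>.samples.tsv` (individual id, group label) and
#'     `<prefix>.map` (chromosome, bp, cM, tab-separated).}
#'   \item{`impute`}{IMPUTE-style `<prefix>.hap` (one line per SNP, one
#'     0/1 column per haploid), `<prefix>.legend` (id, position, a0, a1,
#'     chrom), `<prefix>.sample` (id, group), and `<prefix>.map`.}
#' }
#' Coordinates in VCF are 1-based; internal site indices are 0-based
#' half-open at every other boundary.
#'
#' @param panel A [haplotype_panel()].
#' @param prefix Output path prefix.
#' @param format `"vcf"` or `"impute"`.
#' @return The prefix, invisibly.
#' @export
write_panel <- function(panel, prefix, format = c("vcf", "impute")) {
  format <- match.arg(format)
  st <- panel$sites
  sm <- panel$samples
  write_genetic_map(genetic_map(st$chrom, st$pos, st$cm),
                    paste0(prefix, ".map"))
  if (format == "vcf") {
    con <- file(paste0(prefix, ".vcf"), "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=driftpainter",
                 sprintf("##contig=<ID=%s>", unique(st$chrom)),
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
               con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sm$id),
                     collapse = "\t"), con)
    gt <- matrix("", nrow(st), nrow(sm))
    for (i in seq_len(nrow(sm)))
      gt[, i] <- paste0(panel$haps[sm$hap1[i], ], "|",
                        panel$haps[sm$hap2[i], ])
    body <- paste(st$chrom, st$pos,
                  paste0("snp", seq_len(nrow(st))), "A", "G",
                  ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
    readr::write_tsv(sm[, c("id", "group")], paste0(prefix, ".samples.tsv"))
  } else {
    hap_m <- t(panel$haps[c(rbind(sm$hap1, sm$hap2)), , drop = FALSE])
    readr::write_delim(as.data.frame(hap_m), paste0(prefix, ".hap"),
                       delim = " ", col_names = FALSE)
    readr::write_delim(
      data.frame(id = paste0("snp", seq_len(nrow(st))),
                 position = st$pos, a0 = "A", a1 = "G", chrom = st$chrom),
      paste0(prefix, ".legend"), delim = " ")
    readr::write_delim(as.data.frame(sm[, c("id", "group")]),
                       paste0(prefix, ".sample"), delim = " ")
  }
  invisible(prefix)
}

#' Read a haplotype panel from disk
#'
#' Reads a phased VCF (or IMPUTE hap/legend/sample trio) written by
#' [write_panel()] or by other tools. Unphased genotypes are an error
#' (named by record); multi-allelic sites are rejected with a message
#' giving the count. cM positions come from the genetic map, linearly
#' interpolated between map points (boundary-rate extrapolation beyond
#' the ends, with a warning).
#'
#' @param prefix Path prefix (as in [write_panel()]) or a `.vcf` path.
#' @param format `"vcf"` or `"impute"`.
#' @param map A [genetic_map()]; defaults to `<prefix>.map` when present,
#'   else a constant 1.25 cM/Mb.
#' @param groups Optional named vector id -> group label overriding the
#'   sidecar sample table.
#' @return A [haplotype_panel()].
#' @export
read_panel <- function(prefix, format = c("vcf", "impute"), map = NULL,
                       groups = NULL) {
  format <- match.arg(format)
  prefix <- sub("\\.vcf$", "", prefix)
  if (is.null(map) && file.exists(paste0(prefix, ".map")))
    map <- read_genetic_map(paste0(prefix, ".map"))

  if (format == "vcf") {
    lines <- readLines(paste0(prefix, ".vcf"))
    hdr <- lines[startsWith(lines, "#CHROM")]
    if (length(hdr) != 1) abort("malformed VCF: missing #CHROM header")
    cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
    ids <- cols[-(1:9)]
    body <- lines[!startsWith(lines, "#")]
    parts <- strsplit(body, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield != length(cols)))
      abort(sprintf("malformed VCF record at line %d",
                    which(nfield != length(cols))[1] ))
    rec <- do.call(rbind, parts)
    multi <- grepl(",", rec[, 5], fixed = TRUE)
    if (any(multi)) {
      message(sum(multi), " multi-allelic site(s) rejected")
      rec <- rec[!multi, , drop = FALSE]
    }
    gt <- rec[, -(1:9), drop = FALSE]
    gt1 <- substr(gt, 1, 1); sep <- substr(gt, 2, 2); gt2 <- substr(gt, 3, 3)
    if (any(sep != "|")) {
      bad <- which(sep != "|", arr.ind = TRUE)[1, ]
      abort(sprintf("unphased genotype at %s:%s sample %s",
                    rec[bad[1], 1], rec[bad[1], 2], ids[bad[2]]))
    }
    n_ind <- length(ids)
    haps <- matrix(0L, 2 * n_ind, nrow(rec))
    for (i in seq_len(n_ind)) {
      haps[2 * i - 1, ] <- as.integer(gt1[, i])
      haps[2 * i, ] <- as.integer(gt2[, i])
    }
    chrom <- rec[, 1]; pos <- as.integer(rec[, 2])
    grp <- read_group_sidecar(paste0(prefix, ".samples.tsv"), ids, groups)
    samples <- tibble(id = ids, group = grp,
                      hap1 = seq(1L, by = 2L, length.out = n_ind),
                      hap2 = seq(2L, by = 2L, length.out = n_ind))
  } else {
    hap_m <- as.matrix(readr::read_delim(paste0(prefix, ".hap"), delim = " ",
                                         col_names = FALSE, col_types = readr::cols(.default = "i"),
                                         progress = FALSE))
    leg <- readr::read_delim(paste0(prefix, ".legend"), delim = " ",
                             col_types = readr::cols(), progress = FALSE)
    smp <- readr::read_delim(paste0(prefix, ".sample"), delim = " ",
                             col_types = readr::cols(), progress = FALSE)
    haps <- t(hap_m)
    chrom <- if ("chrom" %in% names(leg)) leg$chrom else "chr1"
    pos <- leg$position
    n_ind <- nrow(smp)
    grp <- if (!is.null(groups)) unname(groups[smp$id]) else smp$group
    samples <- tibble(id = smp$id, group = grp,
                      hap1 = seq(1L, by = 2L, length.out = n_ind),
                      hap2 = seq(2L, by = 2L, length.out = n_ind))
  }
  cm <- if (!is.null(map)) interpolate_cm(map, chrom, pos) else
    pos * 1.25e-6 * 1e0   # constant 1.25 cM/Mb fallback
  dimnames(haps) <- NULL
  haplotype_panel(haps, tibble(chrom = chrom, pos = pos, cm = cm), samples)
}

read_group_sidecar <- function(path, ids, groups) {
  if (!is.null(groups)) return(unname(groups[ids]))
  if (file.exists(path)) {
    d <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
    unname(setNames(d$group, d$id)[ids])
  } else rep("ungrouped", length(ids))
}

#' Write painting profiles as ChromoPainter-style tables
#'
#' One tab-separated table per chromosome plus a genome-wide one, rows =
#' recipients, columns = donor groups; separate files for copied lengths
#' (`chunklengths`) and chunk counts (`chunkcounts`).
#'
#' @param profiles A [paint_panel()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- function(tbl, col, tag) {
    w <- tidyr::pivot_wider(tbl, id_cols = "recipient",
                            names_from = "donor_group",
                            values_from = dplyr::all_of(col),
                            values_fill = 0)
    readr::write_tsv(w, file.path(dir, tag))
  }
  for (ch in unique(profiles$chrom)) {
    sub <- as_tibble(profiles) %>% filter(.data$chrom == ch)
    wide(sub, "cm", paste0("chunklengths.", ch, ".tsv"))
    wide(sub, "chunks", paste0("chunkcounts.", ch, ".tsv"))
  }
  g <- genome_profiles(profiles)
  wide(g, "cm", "chunklengths.genome.tsv")
  wide(g, "chunks", "chunkcounts.genome.tsv")
  invisible(dir)
}

#' Write segment calls as BED-like tab-separated text
#'
#' Columns: haploid, chromosome, start_idx, end_idx (0-based half-open
#' SNP indices), source, n_snps, min_posterior.
#'
#' @param segments A `segment_calls` tibble.
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(as_tibble(segments)[, c("haploid", "chrom", "start_idx",
                                           "end_idx", "source", "n_snps",
                                           "min_posterior")], path)
  invisible(path)
}

#' Write coancestry curves as tab-separated text
#'
#' Columns: s1, s2, bin_cm, weight, count, total, value.
#' @param curves A [build_curves()] result.
#' @param path Output path.
#' @export
write_curves <- function(curves, path) {
  readr::write_tsv(as_tibble(curves), path)
  invisible(path)
}

#' Write an admixture-date fit as a structured JSON report
#'
#' Includes the fitted dates in generations, the converted calendar
#' years, per-curve amplitudes and the fit diagnostics.
#' @param fit A [fit_admixture_date()] result.
#' @param path Output path.
#' @export
write_date_fit <- function(fit, path) {
  jsonlite::write_json(
    list(dates = fit$dates, amplitudes = fit$amplitudes,
         rss = fit$rss, null_rss = fit$null_rss,
         r_squared_gain = fit$r_squared_gain, no_signal = fit$no_signal),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write a labelled square matrix (pairwise F, coincidence) as TSV
#'
#' @param m Square matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  readr::write_tsv(as_tibble(as.data.frame(m), rownames = "id"), path)
  invisible(path)
}
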