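#' Simulate a phased haplotype panel under a demographic model
#'
#' Runs a backward-in-time (coalescent-with-recombination) simulation of
#' independent genomic regions under `model`, overlaying binary mutations,
#' and returns the sampled phased haplotypes as a [haplotype_panel()].
#' Regions are statistically independent replicates and are labelled
#' `region01`, `region02`, ... as chromosomes; cM positions follow the
#' constant recombination rate.
#'
#' The heavy lifting is delegated to the bundled msprime driver
#' (`inst/python/simulate_panel.py`), exchanged through temporary files;
#' results are reproducible bit-for-bit given (`seed`, parameters).
#'
#' @param model A [build_demography()] result (or compatible model).
#' @param samples_per_pop Named integer vector: diploid individuals to
#'   sample per population (present-day populations only).
#' @param regions Numeric vector of region lengths in bp
#'   (default ten regions of 5 Mb).
#' @param mutation_rate Per-bp per-generation mutation rate (default 4e-8).
#' @param recombination_rate Per-bp per-generation recombination rate
#'   (default 1.25e-8).
#' @param seed Integer seed (required).
#' @return A [haplotype_panel()] with group labels equal to population
#'   names; individuals are named `<pop>_<i>`.
#' @export
simulate_panel <- function(model, samples_per_pop,
                           regions = rep(5e6, 10),
                           mutation_rate = 4e-8,
                           recombination_rate = 1.25e-8,
                           seed) {
  if (missing(seed)) abort("`seed` is required")
  if (any(regions <= 0)) abort("regions must have positive length")
  if (is.null(names(samples_per_pop)) || any(names(samples_per_pop) == ""))
    abort("`samples_per_pop` must be a named vector")
  leaves <- present_day_pops(model)
  missing_pops <- setdiff(names(samples_per_pop), leaves)
  if (length(missing_pops))
    abort(paste0("cannot sample from populations absent at time 0: ",
                 paste(missing_pops, collapse = ", ")))

  spec <- demography_spec(model, samples_per_pop, regions,
                          recombination_rate, mutation_rate, as.integer(seed))
  td <- tempfile("dpsim")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  spec_path <- file.path(td, "spec.json")
  bin_path <- file.path(td, "panel.bin")
  meta_path <- file.path(td, "meta.json")
  jsonlite::write_json(spec, spec_path, auto_unbox = TRUE, digits = NA)

  driver <- system.file("python", "simulate_panel.py", package = "driftpainter")
  python <- getOption("driftpainter.python", "python")
  status <- system2(python, c(shQuote(driver), shQuote(spec_path),
                              shQuote(bin_path), shQuote(meta_path)),
                    stdout = file.path(td, "out.log"),
                    stderr = file.path(td, "err.log"))
  if (status != 0)
    abort(paste0("coalescent engine failed:\n",
                 paste(readLines(file.path(td, "err.log")), collapse = "\n")))

  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  read_sim_blob(bin_path, meta, recombination_rate)
}

present_day_pops <- function(model) {
  anc <- purrr::map_chr(purrr::keep(model$splits, ~!isTRUE(.x$join)),
                        "ancestral")
  setdiff(model$populations$name, anc)
}

read_sim_blob <- function(bin_path, meta, recombination_rate) {
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  n_reg <- nrow(meta$regions)
  hap_list <- vector("list", n_reg)
  site_list <- vector("list", n_reg)
  for (r in seq_len(n_reg)) {
    hdr <- readBin(con, "integer", n = 2, size = 4)
    n_sites <- hdr[1]; n_hap <- hdr[2]
    pos <- readBin(con, "integer", n = n_sites, size = 4)
    raw <- readBin(con, "raw", n = as.numeric(n_sites) * n_hap)
    g <- matrix(as.integer(raw), nrow = n_hap, byrow = TRUE)
    hap_list[[r]] <- g
    site_list[[r]] <- tibble(
      chrom = sprintf("region%02d", r), pos = pos,
      cm = pos * recombination_rate * 100)
  }
  haps <- do.call(cbind, hap_list)
  sites <- bind_rows(site_list)
  pops <- meta$hap_pop[seq(1, length(meta$hap_pop), by = 2)]
  idx <- stats::ave(seq_along(pops), pops, FUN = seq_along)
  samples <- tibble(id = paste0(pops, "_", idx), group = pops,
                    hap1 = seq(1L, by = 2L, length.out = length(pops)),
                    hap2 = seq(2L, by = 2L, length.out = length(pops)))
  haplotype_panel(haps, sites, samples)
}
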