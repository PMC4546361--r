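#' Run a full painting analysis pipeline
#'
#' Chains the stages -- panel acquisition (simulated preset or files),
#' optional SNP ascertainment, painting under one or more donor-set
#' analyses, group aggregation, NNLS ancestry cleaning with jackknife
#' errors, profile-comparison statistics, and optional
#' Dirichlet-multinomial clustering -- into one reproducible run with a
#' deterministic output layout and a manifest recording every seed and
#' parameter.
#'
#' @param config A named list or path to a YAML file. Recognised blocks:
#' \describe{
#'   \item{`panel`}{Either `preset`, `samples_per_pop`, `regions`,
#'     `mutation_rate`, `recombination_rate` (simulated), or `path`,
#'     `format` (files).}
#'   \item{`ascertainment`}{`n_per_region` (optional; target spectrum
#'     defaults to the panel's own).}
#'   \item{`analyses`}{Named list; each entry has `mode` and optional
#'     `groups` (see [donor_set()]).}
#'   \item{`recipients`}{Optional individual ids to paint (default all).}
#'   \item{`targets`}{Groups to clean into ancestry profiles (default all
#'     painted groups).}
#'   \item{`params`}{Optional `switch_rate` / `emission_rate`.}
#'   \item{`cluster`}{Optional: `groups` (two labels), plus
#'     [cluster_config()] fields.}
#'   \item{`seed`}{Base seed (required).}
#'   \item{`out_dir`}{Output directory (optional: no files written when
#'     absent).}
#' }
#' @return A result bundle (list) with elements `panel`, and per analysis
#'   `profiles`, `ancestry` (named list of [ancestry_profile()]s),
#'   `comparisons`, and optionally `cluster`; plus `manifest`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) abort("config must provide `seed`")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir

  panel <- acquire_panel(config, seed)
  if (!is.null(config$ascertainment)) {
    asc <- config$ascertainment
    panel <- ascertain_snps(panel, n_per_region = asc$n_per_region,
                            seed = seed + 1L)
  }

  bundle <- list(panel = panel, analyses = list())
  manifest <- list(seed = seed, config = config,
                   package_version = as.character(utils::packageVersion("driftpainter")),
                   n_sites = nrow(panel$sites),
                   groups = panel_groups(panel))

  for (an in names(config$analyses)) {
    spec <- config$analyses[[an]]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        abort(paste0("stage `", what, "` failed in analysis ", an, ": ",
                     conditionMessage(e))))
    }
    ds <- donor_set(spec$mode %||% "all_donors",
                    groups = unlist(spec$groups) %||% character())
    params <- if (!is.null(config$params))
      copy_model_params(config$params$switch_rate,
                        config$params$emission_rate %||% 0.00771) else NULL
    recipients <- config$recipients %||% panel$samples$id
    profiles <- stage("painting",
                      paint_panel(panel, ds, recipients = recipients,
                                  params = params))
    targets <- config$targets %||% unique(profiles$recipient_group)
    ancestry <- stage("profiles", {
      res <- lapply(targets, function(tg)
        ancestry_profile(profiles, tg))
      names(res) <- targets
      res
    })
    comparisons <- stage("stats", compare_profiles(profiles, "group"))
    out <- list(donor_set = ds, profiles = profiles, ancestry = ancestry,
                comparisons = comparisons)

    if (!is.null(config$cluster)) {
      cl <- config$cluster
      cc <- cluster_config(C = cl$C %||% 2, delta = cl$delta %||% 100,
                           M = cl$M %||% 200000,
                           burn_in = cl$burn_in %||% (cl$M %||% 200000) / 2,
                           thin = cl$thin %||% 1000,
                           n_chains = cl$n_chains %||% 10)
      sub <- profiles %>%
        filter(.data$recipient_group %in% unlist(cl$groups))
      attributes(sub) <- c(attributes(sub),
                           attributes(profiles)[c("chrom_info", "donor_groups",
                                                  "params", "level")])
      class(sub) <- class(profiles)
      out$cluster <- stage("cluster",
                           run_gibbs(sub, cc, seed = seed + 100L))
    }
    bundle$analyses[[an]] <- out

    if (!is.null(out_dir)) {
      adir <- file.path(out_dir, an)
      write_profiles(profiles, file.path(adir, "profiles"))
      anc_tbl <- purrr::imap_dfr(ancestry, function(a, tg)
        as_tibble(a) %>% mutate(target = tg, .before = 1))
      readr::write_tsv(anc_tbl, file.path(adir, "ancestry.tsv"))
      readr::write_tsv(comparisons, file.path(adir, "comparisons.tsv"))
      if (!is.null(out$cluster))
        readr::write_tsv(as_tibble(coincidence_matrix(out$cluster),
                                   rownames = "id"),
                         file.path(adir, "coincidence.tsv"))
    }
  }
  bundle$manifest <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(bundle)
}

acquire_panel <- function(config, seed) {
  p <- config$panel
  if (is.null(p)) abort("config must provide a `panel` block")
  if (!is.null(p$preset)) {
    model <- build_demography(p$preset, split = p$split, pulse = p$pulse)
    simulate_panel(model,
                   samples_per_pop = unlist(p$samples_per_pop),
                   regions = p$regions %||% rep(5e6, 10),
                   mutation_rate = p$mutation_rate %||% 4e-8,
                   recombination_rate = p$recombination_rate %||% 1.25e-8,
                   seed = seed)
  } else if (!is.null(p$path)) {
    read_panel(p$path, format = p$format %||% "vcf")
  } else abort("panel block needs either `preset` or `path`")
}
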