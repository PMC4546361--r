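#' Default switch rate for the copying model
#'
#' The copying-model switch rate is fixed, per analysis, to 400000 divided
#' by the total number of donor haploids in that analysis.
#'
#' @param n_donor_haploids Positive integer count of donor haploids.
#' @return The default switch rate (per Morgan).
#' @examples
#' default_switch_rate(2 * 21 + 2 * 28)  # 170.068
#' @export
default_switch_rate <- function(n_donor_haploids) {
  if (n_donor_haploids < 1) abort("need at least one donor haploid")
  400000 / n_donor_haploids
}

#' Copying-model parameters
#'
#' @param switch_rate Expected switches per Morgan (> 0).
#' @param emission_rate Per-site miscopy probability in `[0, 0.5)`.
#' @return A `copy_model_params` list.
#' @export
copy_model_params <- function(switch_rate, emission_rate = 0.00771) {
  if (switch_rate <= 0) abort("`switch_rate` must be > 0")
  if (emission_rate < 0 || emission_rate >= 0.5)
    abort("`emission_rate` must lie in [0, 0.5)")
  structure(list(switch_rate = switch_rate, emission_rate = emission_rate),
            class = "copy_model_params")
}

#' Donor-set specification
#'
#' Selects which groups may act as donors. The recipient's own two haploids
#' are always excluded regardless of mode ("individuals are not allowed to
#' copy from themselves"); group-level exclusion happens only through
#' `exclude_groups` / `include_groups`.
#'
#' @param mode `"all_donors"`, `"exclude_groups"` or `"include_groups"`.
#' @param groups Group labels to exclude (or include, per `mode`).
#' @return A `donor_set` list.
#' @export
donor_set <- function(mode = c("all_donors", "exclude_groups",
                               "include_groups"),
                      groups = character()) {
  mode <- match.arg(mode)
  if (mode != "all_donors" && length(groups) == 0)
    abort("`groups` required for this mode")
  structure(list(mode = mode, groups = groups), class = "donor_set")
}

#' Donor haploid rows for a recipient under a donor-set spec
#' @noRd
resolve_donor_rows <- function(panel, spec, recipient_id = NULL) {
  groups <- switch(spec$mode,
    all_donors = panel_groups(panel),
    exclude_groups = setdiff(panel_groups(panel), spec$groups),
    include_groups = intersect(panel_groups(panel), spec$groups))
  rows <- group_hap_rows(panel, groups)
  if (!is.null(recipient_id)) {
    s <- panel$samples[panel$samples$id == recipient_id, ]
    rows <- setdiff(rows, c(s$hap1, s$hap2))
  }
  if (length(rows) == 0) abort("empty donor set after exclusions")
  rows
}

#' Per-site cM weights within one chromosome (midpoint rule)
#' @noRd
site_weights_cm <- function(cm) {
  L <- length(cm)
  if (L == 1) return(1e-8)
  d <- pmax(diff(cm), 1e-8)
  c(d[1] / 2, if (L > 2) (d[-(L - 1)] + d[-1]) / 2 else NULL, d[L - 1] / 2)
}

#' Inter-site distances in Morgans, zero gaps clamped to 1e-8 cM
#' @noRd
site_gaps_morgan <- function(cm) pmax(diff(cm), 1e-8) / 100

#' Paint one haploid genome against a set of donor haploids
#'
#' Runs the forward--backward recursions of the copying HMM on each
#' chromosome, returning expected copied lengths and chunk counts per donor
#' group and (optionally) per-site posterior copy probabilities.
#'
#' @param panel A [haplotype_panel()].
#' @param haploid Row index of the recipient haploid in `panel$haps`.
#' @param donor_rows Row indices of the donor haploids (must not contain
#'   `haploid`).
#' @param params A [copy_model_params()].
#' @param prior_weights Optional named per-group prior weights for the
#'   landing probabilities (default uniform over donor haploids).
#' @param site_posterior Return per-site group posteriors?
#' @param n_samples Number of copy-paths to sample from the posterior.
#' @return A list: `profile` tibble (`chrom`, `donor_group`, `cm`,
#'   `chunks`), `loglik`, and, when requested, `site_posterior` (tibble
#'   with `chrom`, `site`, one column per donor group) and `paths`
#'   (list of matrices of donor rows, one per chromosome).
#' @export
paint_haploid <- function(panel, haploid, donor_rows, params,
                          prior_weights = NULL, site_posterior = FALSE,
                          n_samples = 0) {
  if (haploid %in% donor_rows) abort("recipient cannot be its own donor")
  if (length(donor_rows) == 0) abort("empty donor set")
  grp <- hap_group(panel)[donor_rows]
  donor_groups <- sort(unique(grp))
  g0 <- match(grp, donor_groups) - 1L
  prior <- donor_prior(grp, donor_groups, prior_weights)

  chroms <- unique(panel$sites$chrom)
  prof <- vector("list", length(chroms))
  sp <- if (site_posterior) vector("list", length(chroms)) else NULL
  paths <- if (n_samples > 0) vector("list", length(chroms)) else NULL
  loglik <- 0
  for (ci in seq_along(chroms)) {
    idx <- which(panel$sites$chrom == chroms[ci])
    cm <- panel$sites$cm[idx]
    res <- cp_hmm_cpp(panel$haps[donor_rows, idx, drop = FALSE],
                      panel$haps[haploid, idx],
                      site_gaps_morgan(cm), params$switch_rate,
                      params$emission_rate, prior, g0,
                      length(donor_groups), site_weights_cm(cm),
                      site_posterior, n_samples)
    loglik <- loglik + res$loglik
    prof[[ci]] <- tibble(chrom = chroms[ci], donor_group = donor_groups,
                         cm = as.numeric(res$f_cm),
                         chunks = as.numeric(res$chunks))
    if (site_posterior) {
      m <- res$site_post
      colnames(m) <- donor_groups
      sp[[ci]] <- bind_cols(tibble(chrom = chroms[ci], site = idx),
                            as_tibble(m))
    }
    if (n_samples > 0) {
      p <- res$paths
      p[] <- donor_rows[p]       # back to panel row indices
      paths[[ci]] <- p
    }
  }
  out <- list(profile = bind_rows(prof), loglik = loglik)
  if (site_posterior) out$site_posterior <- bind_rows(sp)
  if (n_samples > 0) out$paths <- setNames(paths, chroms)
  out
}

hap_group <- function(panel) {
  g <- character(nrow(panel$haps))
  g[panel$samples$hap1] <- panel$samples$group
  g[panel$samples$hap2] <- panel$samples$group
  g
}

donor_prior <- function(grp, donor_groups, prior_weights) {
  if (is.null(prior_weights)) {
    rep(1 / length(grp), length(grp))
  } else {
    w <- prior_weights[grp]
    if (anyNA(w)) abort("prior weights missing for some donor groups")
    cnt <- table(grp)[grp]
    as.numeric(w / as.numeric(cnt)) / sum(prior_weights)
  }
}

#' Paint every recipient individual in a panel
#'
#' Paints both haploids of each recipient against the donor set (always
#' excluding the recipient's own two haploids) and sums the two haploids'
#' expected copied lengths and chunk counts into a per-individual painting
#' profile.
#'
#' @param panel A [haplotype_panel()].
#' @param donors A [donor_set()] (default: all donors).
#' @param recipients Individual ids to paint (default: all individuals).
#' @param params A [copy_model_params()]; when `NULL` the switch rate
#'   defaults to [default_switch_rate()] of the analysis' donor-haploid
#'   count and the emission rate to its default.
#' @return A tibble of class `painting_profiles` with columns `recipient`,
#'   `recipient_group`, `chrom`, `donor_group`, `cm` (expected copied cM),
#'   `chunks`, `f` (within-chromosome copied fraction). Attributes carry
#'   the per-chromosome SNP counts, the donor-group axis and the
#'   parameters used.
#' @export
paint_panel <- function(panel, donors = donor_set("all_donors"),
                        recipients = NULL, params = NULL) {
  recipients <- recipients %||% panel$samples$id
  res <- vector("list", length(recipients))
  for (i in seq_along(recipients)) {
    id <- recipients[i]
    rows <- resolve_donor_rows(panel, donors, recipient_id = id)
    if (is.null(params)) {
      pp <- copy_model_params(default_switch_rate(length(rows)))
    } else pp <- params
    s <- panel$samples[panel$samples$id == id, ]
    p1 <- paint_haploid(panel, s$hap1, rows, pp)
    p2 <- paint_haploid(panel, s$hap2, rows, pp)
    res[[i]] <- p1$profile %>%
      left_join(p2$profile, by = c("chrom", "donor_group"),
                suffix = c("", ".2")) %>%
      mutate(cm = .data$cm + .data$cm.2,
             chunks = .data$chunks + .data$chunks.2,
             recipient = id, recipient_group = s$group) %>%
      select("recipient", "recipient_group", "chrom", "donor_group",
             "cm", "chunks")
  }
  out <- bind_rows(res) %>%
    group_by(.data$recipient, .data$chrom) %>%
    mutate(f = .data$cm / sum(.data$cm)) %>%
    ungroup()
  new_painting_profiles(out, panel, params)
}

new_painting_profiles <- function(tbl, panel, params, level = "individual") {
  structure(tbl,
            class = c("painting_profiles", class(tibble())),
            chrom_info = chrom_info(panel),
            donor_groups = sort(unique(tbl$donor_group)),
            params = params, level = level)
}

#' Genome-wide copying vectors from painting profiles
#'
#' The genome-wide copied fraction is the SNP-count-weighted combination of
#' the per-chromosome expected copied lengths (equivalently, total copied
#' cM normalised over the genome).
#'
#' @param profiles A [paint_panel()] result.
#' @return Tibble `recipient`, `recipient_group`, `donor_group`, `cm`,
#'   `chunks`, `f` with one row per recipient and donor group.
#' @export
genome_profiles <- function(profiles) {
  profiles %>%
    as_tibble() %>%
    group_by(.data$recipient, .data$recipient_group, .data$donor_group) %>%
    summarise(cm = sum(.data$cm), chunks = sum(.data$chunks),
              .groups = "drop_last") %>%
    mutate(f = .data$cm / sum(.data$cm)) %>%
    ungroup()
}

#' Average painting profiles within recipient groups
#'
#' Unweighted mean over individuals within each group, per chromosome and
#' genome-wide.
#'
#' @param profiles A [paint_panel()] result.
#' @param grouping Optional named vector mapping recipient id to group
#'   label (defaults to the panel group labels carried in `profiles`).
#' @return A tibble of class `painting_profiles` at group level, with
#'   `recipient` holding the group label.
#' @export
aggregate_profiles <- function(profiles, grouping = NULL) {
  tbl <- as_tibble(profiles)
  if (!is.null(grouping))
    tbl$recipient_group <- unname(grouping[tbl$recipient])
  if (anyNA(tbl$recipient_group)) abort("grouping misses some recipients")
  out <- tbl %>%
    group_by(.data$recipient_group, .data$chrom, .data$donor_group) %>%
    summarise(cm = mean(.data$cm), chunks = mean(.data$chunks),
              f = mean(.data$f), .groups = "drop") %>%
    mutate(recipient = .data$recipient_group, .before = 1)
  structure(out,
            class = c("painting_profiles", class(tibble())),
            chrom_info = attr(profiles, "chrom_info"),
            donor_groups = attr(profiles, "donor_groups"),
            params = attr(profiles, "params"), level = "group")
}

#' Average copied-segment (chunk) length of a painting profile
#'
#' Total copied proportion divided by total expected chunk count, scaled to
#' the cM length of the painted genome: with everything copied as a single
#' chunk on a 100 cM chromosome this is 100 cM; with two chunks, 50 cM.
#'
#' @param profile Rows of a `painting_profiles` tibble for one recipient.
#' @param total_cm Total painted genome length in cM. Default: twice the
#'   chromosome cM spans (diploid painting) when profiles carry
#'   `chrom_info`; for a single-haploid profile pass the haploid span.
#' @return Average chunk length in cM.
#' @export
average_chunk_length <- function(profile, total_cm = NULL) {
  tot_chunks <- sum(profile$chunks)
  if (tot_chunks <= 0) abort("total expected chunk count is zero")
  if (is.null(total_cm)) total_cm <- sum(profile$cm)
  total_cm / tot_chunks
}

#' Sample copy-paths from the painting posterior
#'
#' Draws complete donor mosaics (per-site donor haploid) from the posterior
#' over copy-paths by backward sampling, and tabulates their chunks: a
#' chunk is a maximal run of sites copied intact from a single donor
#' haploid.
#'
#' @inheritParams paint_haploid
#' @param donors A [donor_set()].
#' @param n_samples Number of paths to draw.
#' @param seed Integer seed.
#' @return A list: `chunks` (tibble `sample`, `chrom`, `start_cm`,
#'   `end_cm`, `mid_cm`, `size_cm`, `donor_hap`, `donor_group`) and
#'   `paths` (per-chromosome matrices of donor rows, rows = samples).
#' @export
sample_paintings <- function(panel, haploid, donors, params, n_samples,
                             seed, prior_weights = NULL) {
  if (missing(seed)) abort("`seed` is required")
  set.seed(as.integer(seed))
  id <- panel$samples$id[panel$samples$hap1 == haploid |
                           panel$samples$hap2 == haploid]
  rows <- resolve_donor_rows(panel, donors,
                             recipient_id = if (length(id)) id else NULL)
  res <- paint_haploid(panel, haploid, rows, params,
                       prior_weights = prior_weights, n_samples = n_samples)
  grp <- hap_group(panel)
  chunk_list <- list()
  for (ch in names(res$paths)) {
    idx <- which(panel$sites$chrom == ch)
    cm <- panel$sites$cm[idx]
    bounds <- chunk_bounds_cm(cm)
    p <- res$paths[[ch]]
    for (s in seq_len(nrow(p))) {
      r <- rle(p[s, ])
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      chunk_list[[length(chunk_list) + 1]] <- tibble(
        sample = s, chrom = ch,
        start_cm = bounds$start[starts], end_cm = bounds$end[ends],
        donor_hap = r$values)
    }
  }
  chunks <- bind_rows(chunk_list) %>%
    mutate(size_cm = .data$end_cm - .data$start_cm,
           mid_cm = (.data$start_cm + .data$end_cm) / 2,
           donor_group = grp[.data$donor_hap])
  list(chunks = chunks, paths = res$paths)
}

# chunk boundaries: midpoints between adjacent sites, chromosome ends at
# the terminal sites
chunk_bounds_cm <- function(cm) {
  L <- length(cm)
  if (L == 1) return(list(start = cm, end = cm))
  mids <- (cm[-L] + cm[-1]) / 2
  list(start = c(cm[1], mids), end = c(mids, cm[L]))
}
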