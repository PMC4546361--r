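#' Demographic models for the synthetic-data generator
#'
#' Builds one of the study's demographic scenarios as a fully specified
#' model: population sizes, split times, instantaneous size changes
#' (bottlenecks), one-way migration pulses and migration ramps. Times are
#' generations before present; sizes are diploid effective sizes; migration
#' rates are per-generation migrant fractions of the receiving population.
#'
#' Presets:
#' \describe{
#'   \item{`MA_full`}{13-population "marginalisation" world: Pop5b splits
#'     from Pop5 at 20 generations and instantaneously drops from 20,000 to
#'     200 diploids until the present.}
#'   \item{`RN_full`, `RN_BN`, `RN_BN_80`}{"Remnants" variants: Pop5b splits
#'     1700 generations ago; contributes migrants to Pop5 at 0.005/gen
#'     (`RN_full`, `RN_BN`) or 0.008/gen (`RN_BN_80`) over 200--300
#'     generations ago and to Pop6 at 0.002/gen over the same window;
#'     `RN_BN*` add a 20,000 to 500 bottleneck in Pop5b from 20 generations
#'     ago.}
#'   \item{`simplified_RN`}{7-population remnants grid: Pop4/Pop5 split 700
#'     generations ago; Pop5b split time from
#'     \{750, 800, 900, 1000, 1100, 1200, 1300, 1700\} with paired
#'     bottleneck starts \{40, 40, 35, 35, 35, 30, 30, 20\} (to 5,000
#'     diploids); Pop5b to Pop5 pulse fraction from \{0.5, 0.75, 0.9\}
#'     realised as per-generation rates \{0.005, 0.0075, 0.009\} over
#'     200--300 generations ago.}
#'   \item{`MA_pop5a`}{Marginalisation variant with an unsampled Pop5a that
#'     split from the common Ari lineage \{300, 400, 500\} generations ago
#'     and contributed 15% over 5 generations starting 70 generations ago;
#'     Pop5b bottleneck to 500 from \{30, 35\} generations ago.}
#' }
#'
#' @param preset One of `"MA_full"`, `"RN_full"`, `"RN_BN"`, `"RN_BN_80"`,
#'   `"simplified_RN"`, `"MA_pop5a"`.
#' @param split For `simplified_RN`: the Pop5/Pop5b split time (grid above);
#'   for `MA_pop5a`: the Pop5a split time.
#' @param pulse For `simplified_RN`: the Pop5b-to-Pop5 migrant fraction,
#'   one of 0.5, 0.75, 0.9.
#' @param bottleneck_start,bottleneck_size Override the Pop5b bottleneck
#'   (defaults come from the preset / grid pairing).
#'
#' @return An object of class `demography_model`.
#' @export
build_demography <- function(preset,
                             split = NULL,
                             pulse = NULL,
                             bottleneck_start = NULL,
                             bottleneck_size = NULL) {
  presets <- c("MA_full", "RN_full", "RN_BN", "RN_BN_80",
               "simplified_RN", "MA_pop5a")
  if (!is.character(preset) || length(preset) != 1 || !(preset %in% presets))
    abort(paste0("unknown preset; valid presets: ",
                 paste(presets, collapse = ", ")))
  model <- switch(preset,
    MA_full = demog_full(variant = "MA"),
    RN_full = demog_full(variant = "RN"),
    RN_BN = demog_full(variant = "RN_BN"),
    RN_BN_80 = demog_full(variant = "RN_BN_80"),
    simplified_RN = demog_simplified(split, pulse,
                                     bottleneck_start, bottleneck_size),
    MA_pop5a = demog_pop5a(split, bottleneck_start))
  model$preset <- preset
  validate_demography(model)
  model
}

new_demography <- function(populations, splits, size_changes = list(),
                           pulses = list(), ramps = list(), params = list()) {
  structure(list(populations = populations, splits = splits,
                 size_changes = size_changes, pulses = pulses,
                 ramps = ramps, params = params),
            class = "demography_model")
}

validate_demography <- function(m) {
  times <- c(purrr::map_dbl(m$splits, "time"),
             purrr::map_dbl(m$size_changes, "time"))
  if (length(times) && any(times <= 0)) abort("event times must be > 0")
  rates <- purrr::map_dbl(m$pulses, "rate")
  if (length(rates) && (any(rates < 0) | any(rates > 1)))
    abort("migrant fractions must lie in [0, 1]")
  # backward-looking split graph must be a tree: every population is
  # derived at most once
  derived <- unlist(purrr::map(m$splits, "derived"))
  if (anyDuplicated(derived)) abort("split graph is not a tree")
  invisible(m)
}

#' @export
print.demography_model <- function(x, ...) {
  cat(sprintf("<demography_model: %s> %d populations, %d splits, %d pulses\n",
              x$preset %||% "custom", nrow(x$populations),
              length(x$splits), length(x$pulses)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pop_tbl <- function(...) {
  d <- list(...)
  tibble(name = names(d), size = unlist(d))
}
split_ev <- function(time, derived, ancestral, join = FALSE)
  list(time = time, derived = derived, ancestral = ancestral, join = join)
size_ev <- function(time, population, size)
  list(time = time, population = population, size = size)
pulse_ev <- function(source, dest, time_start, time_end, rate)
  list(source = source, dest = dest, time_start = time_start,
       time_end = time_end, rate = rate)

# 13-population world shared by the MA and RN full scenarios. African
# populations (1-7, 5b pre-bottleneck) have size 20,000 back to 1,800
# generations ago and 10,000 before; the out-of-Africa branch drops to
# 2,000 for the 500 generations following the 2,500-generation split, and
# the East-Asian ancestor to 2,000 for the 200 generations following the
# 1,000-generation split.
demog_full <- function(variant) {
  pops <- pop_tbl(Pop1 = 20000, Pop2 = 20000, Pop3 = 20000, Pop4 = 20000,
                  Pop5 = 20000, Pop5b = 20000, Pop6 = 20000, Pop7 = 20000,
                  Pop8 = 10000, Pop9 = 10000, Pop10 = 10000,
                  Pop11 = 10000, Pop12 = 10000,
                  anc89 = 10000, anc1112 = 10000, anc810 = 10000,
                  anc23 = 20000, anc56 = 20000, anc57 = 20000,
                  anc812 = 10000, anc47 = 20000, anc27 = 10000,
                  anc212 = 10000, root = 10000)
  splits <- list(
    split_ev(100, c("Pop8", "Pop9"), "anc89"),
    split_ev(375, c("Pop11", "Pop12"), "anc1112"),
    split_ev(400, c("anc89", "Pop10"), "anc810"),
    split_ev(500, c("Pop2", "Pop3"), "anc23"),
    split_ev(700, c("Pop5", "Pop6"), "anc56"),
    split_ev(1000, c("anc56", "Pop7"), "anc57"),
    split_ev(1000, c("anc810", "anc1112"), "anc812"),
    split_ev(1800, c("anc23", "anc47"), "anc27"),
    split_ev(2500, c("anc27", "anc812"), "anc212"),
    split_ev(4000, c("Pop1", "anc212"), "root"))
  size_changes <- list(
    size_ev(800, "anc1112", 2000),    # East-Asian ancestor bottleneck
    size_ev(2000, "anc812", 2000))    # out-of-Africa bottleneck
  pulses <- list(
    pulse_ev("Pop10", "Pop5", 100, 110, 0.02),
    pulse_ev("Pop10", "Pop6", 100, 110, 0.02))
  ramps <- list(list(pop_a = "Pop11", pop_b = "Pop12",
                     step = 0.00025, duration = 375))

  if (variant == "MA") {
    pops$size[pops$name == "Pop5b"] <- 200
    splits <- c(splits, list(
      split_ev(20, "Pop5b", "Pop5", join = TRUE),
      split_ev(1700, c("Pop4", "anc57"), "anc47")))
  } else {
    splits <- c(splits, list(
      split_ev(1700, c("Pop4", "anc57", "Pop5b"), "anc47")))
    rate5 <- if (variant == "RN_BN_80") 0.008 else 0.005
    pulses <- c(pulses, list(
      pulse_ev("Pop5b", "Pop5", 200, 300, rate5),
      pulse_ev("Pop5b", "Pop6", 200, 300, 0.002),
      pulse_ev("Pop10", "Pop5b", 100, 110, 0.02)))
    if (variant %in% c("RN_BN", "RN_BN_80")) {
      pops$size[pops$name == "Pop5b"] <- 500
      size_changes <- c(size_changes, list(size_ev(20, "Pop5b", 20000)))
    }
  }
  new_demography(pops, splits, size_changes, pulses, ramps,
                 params = list(variant = variant))
}

simplified_grid <- tibble(
  split = c(750, 800, 900, 1000, 1100, 1200, 1300, 1700),
  bottleneck_start = c(40, 40, 35, 35, 35, 30, 30, 20))

demog_simplified <- function(split, pulse, bottleneck_start, bottleneck_size) {
  split <- split %||% 1700
  pulse <- pulse %||% 0.5
  if (!(split %in% simplified_grid$split))
    abort(paste0("split time must be one of {",
                 paste(simplified_grid$split, collapse = ", "), "}"))
  if (!(pulse %in% c(0.5, 0.75, 0.9)))
    abort("pulse fraction must be one of {0.5, 0.75, 0.9}")
  bn_start <- bottleneck_start %||%
    simplified_grid$bottleneck_start[simplified_grid$split == split]
  bn_size <- bottleneck_size %||% 5000
  rate5 <- pulse / 100   # spread over the 100-generation window

  pops <- pop_tbl(Pop1 = 20000, Pop2 = 20000, Pop3 = 20000, Pop4 = 20000,
                  Pop5 = 20000, Pop5b = bn_size, Pop6 = 10000,
                  anc12 = 20000, anc45 = 20000, anc35 = 20000,
                  ancAfr = 10000, root = 10000)
  splits <- list(
    split_ev(500, c("Pop1", "Pop2"), "anc12"),
    split_ev(700, c("Pop4", "Pop5"), "anc45"),
    split_ev(1800, c("anc12", "anc35"), "ancAfr"),
    split_ev(2500, c("ancAfr", "Pop6"), "root"))
  if (split == 1700) {
    splits <- c(splits, list(split_ev(1700, c("Pop3", "anc45", "Pop5b"), "anc35")))
  } else {
    splits <- c(splits, list(
      split_ev(1700, c("Pop3", "anc45"), "anc35"),
      split_ev(split, "Pop5b", if (split > 700) "anc45" else "Pop5",
               join = TRUE)))
  }
  size_changes <- list(
    size_ev(bn_start, "Pop5b", 20000),
    size_ev(2000, "Pop6", 2000))
  pulses <- list(
    pulse_ev("Pop6", "Pop4", 100, 110, 0.04),
    pulse_ev("Pop6", "Pop5", 100, 110, 0.02),
    pulse_ev("Pop6", "Pop5b", 100, 110, 0.02),
    pulse_ev("Pop5b", "Pop4", 200, 300, 0.001),
    pulse_ev("Pop5b", "Pop5", 200, 300, rate5))
  new_demography(pops, splits, size_changes, pulses,
                 params = list(split = split, pulse = pulse,
                               bottleneck_start = bn_start,
                               bottleneck_size = bn_size))
}

demog_pop5a <- function(split, bottleneck_start) {
  split <- split %||% 400
  bn_start <- bottleneck_start %||% 30
  if (!(split %in% c(300, 400, 500)))
    abort("split time must be one of {300, 400, 500}")
  if (!(bn_start %in% c(30, 35)))
    abort("bottleneck start must be one of {30, 35}")
  pops <- pop_tbl(Pop1 = 20000, Pop2 = 20000, Pop3 = 20000, Pop4 = 20000,
                  Pop5 = 20000, Pop5a = 20000, Pop5b = 500, Pop6 = 10000,
                  anc12 = 20000, anc45 = 20000, anc35 = 20000,
                  ancAfr = 10000, root = 10000)
  splits <- list(
    split_ev(bn_start, "Pop5b", "Pop5", join = TRUE),
    split_ev(split, "Pop5a", "Pop5", join = TRUE),
    split_ev(500, c("Pop1", "Pop2"), "anc12"),
    split_ev(700, c("Pop4", "Pop5"), "anc45"),
    split_ev(1700, c("Pop3", "anc45"), "anc35"),
    split_ev(1800, c("anc12", "anc35"), "ancAfr"),
    split_ev(2500, c("ancAfr", "Pop6"), "root"))
  size_changes <- list(size_ev(2000, "Pop6", 2000))
  pulses <- list(
    pulse_ev("Pop6", "Pop4", 100, 110, 0.04),
    pulse_ev("Pop6", "Pop5", 100, 110, 0.02),
    pulse_ev("Pop5a", "Pop5", 65, 70, 0.03))
  new_demography(pops, splits, size_changes, pulses,
                 params = list(split = split, bottleneck_start = bn_start))
}

#' Serialise a demography (plus run parameters) for the coalescent engine
#' @noRd
demography_spec <- function(model, samples, region_lengths,
                            recombination_rate, mutation_rate, seed) {
  list(populations = purrr::map2(model$populations$name,
                                 model$populations$size,
                                 ~list(name = .x, size = .y)),
       splits = purrr::map(model$splits, function(s)
         list(time = s$time, derived = as.list(s$derived),
              ancestral = s$ancestral, join = isTRUE(s$join))),
       size_changes = model$size_changes,
       pulses = purrr::map(model$pulses, function(p)
         list(time_start = p$time_start, time_end = p$time_end,
              source = p$source, dest = p$dest, rate = p$rate)),
       ramps = model$ramps,
       samples = as.list(samples),
       region_lengths = as.list(region_lengths),
       recombination_rate = recombination_rate,
       mutation_rate = mutation_rate,
       seed = seed)
}

#' Write a demography preset to a YAML configuration file
#' @param model A [build_demography()] result.
#' @param path File path.
#' @export
write_demography_yaml <- function(model, path) {
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}
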