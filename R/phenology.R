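# Thermal-time phenology with a triple broken-linear photoperiod response.
#
# Development is clocked by degree-days above a base temperature. The duration
# of the phase from end of juvenile to panicle initiation is extended under
# long days between the minimum (Ppcrit1) and maximum (Ppcrit2) photoperiods
# at a cultivar-specific slope (Ppslope), which is what lets photoperiod-
# sensitive Malian landraces flower in a narrow September window regardless of
# sowing date. Stage boundaries are tracked on the continuous cumulative
# degree-day axis: excess thermal time beyond a stage target is carried into
# the next stage, so phase durations in degree-days equal their targets
# exactly.

PHENO_STAGES <- c("presowing", "sowing", "emergence", "end_juvenile",
                  "panicle_initiation", "flag_leaf", "flowering",
                  "start_grain_fill", "maturity", "ripe")

#' Cultivar coefficient presets
#'
#' Returns the full coefficient set for one of the two parameterized Malian
#' Guinea-type landraces: \code{"CSM63E"} (early maturing, weakly
#' photoperiod-sensitive, Sahelian zone) or \code{"CSM335"} (medium maturing,
#' photoperiod-sensitive, Sudanian zone). Photoperiod-response, phase-duration,
#' grain and leaf-area coefficients are the published parameterization;
#' cardinal temperatures (11/30/42 deg C), plastochron (34 deg Cd),
#' phyllochron (40 deg Cd), embryo leaf number (4) and the lumped
#' sowing-to-end-juvenile duration (200 deg Cd) are conventional sorghum
#' values, all overridable via \code{...}. The plastochron default (21 deg Cd
#' per initiated leaf) follows the APSIM sorghum leaf initiation rate and
#' reproduces observed main-stem leaf numbers (about 21 for CSM63E and
#' 28 or more for CSM335 at early Sudanian sowings).
#'
#' @param name Preset name, or a custom name when all coefficients are passed.
#' @param ... Named coefficient overrides.
#' @return An object of class \code{cultivar_params}.
#' @examples
#' cultivar("CSM335")$ppslope   # 226 deg Cd per hour
#' @export
cultivar <- function(name = c("CSM63E", "CSM335"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    ppcrit1 = 11.5, ppcrit2 = 13.5,
    tt_endjuv_to_init_base = 50,
    tt_flag_to_flower = 170,
    tt_flower_to_start_grain = 80,
    tt_maturity_to_ripe = 1,
    plastochron = 21, phyllochron = 40, embryo_leaves = 4,
    tt_sow_to_emergence = 60, tt_sow_to_endjuv = 200,
    t_base = 11, t_opt = 30, t_max = 42
  )
  spec <- if (name == "CSM63E") {
    list(ppslope = 126, tt_flower_to_maturity = 484, dm_per_seed = 0.00083,
         max_gf_rate = 0.090, largest_leaf_multiplier = 0.783,
         amax_slope = 17.163, amax_intercept = -71.354)
  } else {
    list(ppslope = 226, tt_flower_to_maturity = 518, dm_per_seed = 0.0015,
         max_gf_rate = 0.045, largest_leaf_multiplier = 0.698,
         amax_slope = 32.9, amax_intercept = -296)
  }
  out <- utils::modifyList(c(base, spec), list(...))
  validate_cultivar(out)
}

validate_cultivar <- function(x) {
  stopifnot(is.list(x), !is.null(x$name))
  if (x$ppcrit1 >= x$ppcrit2) stop("Ppcrit1 must be < Ppcrit2", call. = FALSE)
  if (x$ppslope < 0) stop("Ppslope must be >= 0", call. = FALSE)
  durs <- c(x$tt_endjuv_to_init_base, x$tt_flag_to_flower,
            x$tt_flower_to_start_grain, x$tt_flower_to_maturity,
            x$tt_maturity_to_ripe, x$tt_sow_to_endjuv, x$tt_sow_to_emergence)
  if (any(durs < 0)) stop("thermal durations must be >= 0", call. = FALSE)
  if (x$tt_sow_to_emergence > x$tt_sow_to_endjuv) {
    stop("tt_sow_to_emergence must not exceed tt_sow_to_endjuv", call. = FALSE)
  }
  if (!(x$t_base < x$t_opt && x$t_opt < x$t_max)) {
    stop("cardinal temperatures must satisfy base < optimum < maximum", call. = FALSE)
  }
  structure(x, class = "cultivar_params")
}

#' Read/write cultivar coefficient files
#'
#' Coefficients are stored as a flat YAML map; the two presets round-trip
#' exactly.
#'
#' @param x A \code{cultivar_params} object.
#' @param path File path.
#' @return \code{read_cultivar} returns a \code{cultivar_params};
#'   \code{write_cultivar} returns \code{path} invisibly.
#' @export
write_cultivar <- function(x, path) {
  stopifnot(inherits(x, "cultivar_params"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname write_cultivar
#' @export
read_cultivar <- function(path) {
  validate_cultivar(yaml::read_yaml(path))
}

#' Daily thermal time (degree-days)
#'
#' Broken-linear response on the daily mean temperature: zero at or below the
#' base, rising linearly to a maximum at the optimum, then declining linearly
#' to zero at the maximum temperature.
#'
#' @param tmax,tmin Daily extremes, deg C (\code{tmax >= tmin}).
#' @param cultivar A \code{\link{cultivar}} (supplies cardinal temperatures).
#' @return Degree-days, vectorized over inputs.
#' @examples
#' daily_thermal_time(30, 22, cultivar("CSM63E"))  # mean 26 -> 15 deg Cd
#' @export
daily_thermal_time <- function(tmax, tmin, cultivar) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin", call. = FALSE)
  tm <- (tmax + tmin) / 2
  tb <- cultivar$t_base; to <- cultivar$t_opt; tx <- cultivar$t_max
  ifelse(tm <= tb, 0,
         ifelse(tm <= to, tm - tb,
                ifelse(tm >= tx, 0, (tx - tm) / (tx - to) * (to - tb))))
}

#' Duration of end-of-juvenile to panicle initiation
#'
#' The triple broken-linear photoperiod response: a base duration below
#' Ppcrit1, linear extension at Ppslope degree-days per hour between the
#' critical photoperiods, and a plateau at and above Ppcrit2.
#'
#' @param photoperiod Day length including twilight, h, in (0, 24).
#' @param cultivar A \code{\link{cultivar}}.
#' @return Phase duration in degree-days, vectorized over photoperiod.
#' @examples
#' endjuv_to_init_duration(11.0, cultivar("CSM335"))   # base 50
#' endjuv_to_init_duration(13.5, cultivar("CSM63E"))   # plateau 302
#' @export
endjuv_to_init_duration <- function(photoperiod, cultivar) {
  if (any(photoperiod <= 0 | photoperiod >= 24)) {
    stop("photoperiod must lie in (0, 24) hours", call. = FALSE)
  }
  excess <- pmin(pmax(photoperiod - cultivar$ppcrit1, 0),
                 cultivar$ppcrit2 - cultivar$ppcrit1)
  cultivar$tt_endjuv_to_init_base + cultivar$ppslope * excess
}

#' Total main-stem leaf number
#'
#' Leaves are initiated at one per plastochron from emergence until panicle
#' initiation, on top of the embryonic leaves; a longer (photoperiod-extended)
#' juvenile phase therefore yields more leaves. Rounded to the nearest
#' integer, ties up.
#'
#' @param tt_emergence_to_init Degree-days from emergence to panicle
#'   initiation, >= 0.
#' @param cultivar A \code{\link{cultivar}}.
#' @return Integer leaf count >= the embryonic number.
#' @examples
#' total_leaf_number(408, cultivar("CSM63E", plastochron = 34))  # 16
#' @export
total_leaf_number <- function(tt_emergence_to_init, cultivar) {
  if (any(tt_emergence_to_init < 0)) stop("thermal time must be >= 0", call. = FALSE)
  as.integer(floor(cultivar$embryo_leaves +
                     tt_emergence_to_init / cultivar$plastochron + 0.5))
}

#' Sowing date from the rainfall trigger rule
#'
#' Scans the sowing window for the first day on which the trailing 7-day rain
#' sum reaches 20 mm and plant-available soil water is at least 10 mm; if no
#' day qualifies, sowing is forced on the last day of the window. The soil
#' state is stepped forward as fallow (rain and bare-soil evaporation only)
#' from \code{start_doy}, so the moisture condition reflects the pre-season
#' water balance.
#'
#' @param weather A \code{daily_weather} series covering the window.
#' @param state A \code{soil_water_state}, valid at \code{start_doy} (typically
#'   a fresh 20% fractional-available-water reset).
#' @param window_start,window_end Day-of-year bounds (defaults June 1 and
#'   July 15).
#' @param start_doy Day from which the fallow balance is run.
#' @param rain_trigger Required trailing 7-day rain sum, mm.
#' @param asw_trigger Required plant-available soil water, mm.
#' @param drainage_coef Passed to \code{\link{step_water_balance}}.
#' @return A list with \code{doy} (sowing day), \code{forced} (logical) and
#'   \code{state} (soil state at dawn of the sowing day).
#' @export
sowing_date <- function(weather, state, window_start = 152, window_end = 196,
                        start_doy = 121, rain_trigger = 20, asw_trigger = 10,
                        drainage_coef = 0.5) {
  stopifnot(window_start <= window_end)
  if (max(weather$doy) < window_end || min(weather$doy) > start_doy) {
    stop("weather series does not cover the sowing window", call. = FALSE)
  }
  for (d in start_doy:window_end) {
    i <- match(d, weather$doy)
    if (d >= window_start) {
      lo <- max(min(weather$doy), d - 6)
      rain7 <- sum(weather$rain[weather$doy >= lo & weather$doy <= d])
      if ((rain7 >= rain_trigger && available_soil_water(state) >= asw_trigger) ||
          d == window_end) {
        return(list(doy = d, forced = d == window_end &&
                      !(rain7 >= rain_trigger &&
                          available_soil_water(state) >= asw_trigger),
                    state = state))
      }
    }
    pe <- potential_soil_evap(state, weather$radn[i], lai = 0)
    state <- step_water_balance(state, weather$rain[i], pe, 0,
                                drainage_coef = drainage_coef)
  }
  list(doy = window_end, forced = TRUE, state = state)
}

#' Initialize a phenology state at sowing
#'
#' @param cultivar A \code{\link{cultivar}}.
#' @param sowing_doy Calendar day of sowing.
#' @return A \code{phenology_state}: the stage machine positioned at sowing
#'   with cumulative thermal time zero.
#' @export
phenology_init <- function(cultivar, sowing_doy = NA_integer_) {
  targets <- c(sowing = 0,
               emergence = cultivar$tt_sow_to_emergence,
               end_juvenile = cultivar$tt_sow_to_endjuv,
               panicle_initiation = NA, flag_leaf = NA, flowering = NA,
               start_grain_fill = NA, maturity = NA, ripe = NA)
  structure(
    list(stage = "sowing", stage_idx = 2L, cum_tt = 0,
         targets = targets,
         transition_tt = c(sowing = 0),
         transition_doy = c(sowing = sowing_doy),
         pp_sum = 0, pp_n = 0L,
         max_leaf_no = NA_integer_, leaves_at_init = NA_real_,
         cultivar = cultivar$name),
    class = "phenology_state"
  )
}

#' Advance the phenology stage machine by one day
#'
#' Accumulates the day's thermal time and fires every stage transition whose
#' cumulative target is reached, crediting excess degree-days to the next
#' phase. While the crop is between end of juvenile and panicle initiation,
#' the phase target is re-evaluated daily from the running mean photoperiod of
#' the days spent in that phase. At panicle initiation the total leaf number is
#' fixed, which sets the panicle-initiation to flag-leaf duration to
#' (remaining leaves) x phyllochron.
#'
#' @param state A \code{phenology_state}.
#' @param daily_tt Degree-days for the day.
#' @param photoperiod Day length (h) for the day.
#' @param cultivar A \code{\link{cultivar}}.
#' @param doy Calendar day (for transition dates).
#' @return The updated \code{phenology_state}.
#' @export
advance_phenology <- function(state, daily_tt, photoperiod, cultivar,
                              doy = NA_integer_) {
  stopifnot(inherits(state, "phenology_state"))
  if (state$stage == "ripe") return(state)
  state$cum_tt <- state$cum_tt + daily_tt

  # photoperiod accumulates while in the photoperiod-sensitive phase
  if (state$stage == "end_juvenile") {
    state$pp_sum <- state$pp_sum + photoperiod
    state$pp_n <- state$pp_n + 1L
    pp_mean <- state$pp_sum / state$pp_n
    state$targets["panicle_initiation"] <- state$targets["end_juvenile"] +
      endjuv_to_init_duration(pp_mean, cultivar)
  }

  repeat {
    nxt <- PHENO_STAGES[match(state$stage, PHENO_STAGES) + 1L]
    if (is.na(nxt)) break
    target <- state$targets[nxt]
    if (is.na(target) || state$cum_tt < target) break

    state$stage <- nxt
    state$transition_tt[nxt] <- unname(target)
    state$transition_doy[nxt] <- doy

    if (nxt == "end_juvenile") {
      # photoperiod-sensitive phase opens; seed its mean with today's value
      state$pp_sum <- photoperiod
      state$pp_n <- 1L
      state$targets["panicle_initiation"] <- target +
        endjuv_to_init_duration(photoperiod, cultivar)
    } else if (nxt == "panicle_initiation") {
      tt_emerg_to_init <- unname(target - state$targets["emergence"])
      state$max_leaf_no <- total_leaf_number(tt_emerg_to_init, cultivar)
      state$leaves_at_init <- min(
        state$max_leaf_no,
        cultivar$embryo_leaves + tt_emerg_to_init / cultivar$phyllochron)
      state$targets["flag_leaf"] <- target +
        max(0, state$max_leaf_no - state$leaves_at_init) * cultivar$phyllochron
    } else if (nxt == "flag_leaf") {
      state$targets["flowering"] <- target + cultivar$tt_flag_to_flower
    } else if (nxt == "flowering") {
      state$targets["start_grain_fill"] <- target + cultivar$tt_flower_to_start_grain
      state$targets["maturity"] <- target + cultivar$tt_flower_to_maturity
    } else if (nxt == "maturity") {
      state$targets["ripe"] <- target + cultivar$tt_maturity_to_ripe
    }
  }
  state
}

#' Calibrate the photoperiod slope from trial observations
#'
#' Ordinary least squares on the linear segment of the photoperiod response:
#' observations whose mean photoperiod lies strictly between the critical
#' photoperiods are regressed as
#' \code{tt = base + slope * (photoperiod - ppcrit1)}.
#'
#' @param observations Data.frame with columns \code{photoperiod} (h) and
#'   \code{tt} (degree-days from end of juvenile to panicle initiation), or a
#'   two-column matrix in that order.
#' @param ppcrit1,ppcrit2 Critical photoperiods bounding the sensitive range.
#' @return A list with \code{slope} (deg Cd per hour), \code{base} (deg Cd, the
#'   duration at Ppcrit1), \code{n_used} and the fitted \code{lm} object.
#' @examples
#' obs <- data.frame(photoperiod = c(12, 12.5, 13),
#'                   tt = 50 + 226 * (c(12, 12.5, 13) - 11.5))
#' fit_ppslope(obs)$slope   # exactly 226
#' @export
fit_ppslope <- function(observations, ppcrit1 = 11.5, ppcrit2 = 13.5) {
  obs <- as.data.frame(observations)
  if (!all(c("photoperiod", "tt") %in% names(obs))) {
    names(obs)[1:2] <- c("photoperiod", "tt")
  }
  keep <- obs$photoperiod > ppcrit1 & obs$photoperiod < ppcrit2
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) < 2 || length(unique(obs$photoperiod)) < 2) {
    stop("slope unidentifiable: need >= 2 distinct photoperiods strictly ",
         "inside (", ppcrit1, ", ", ppcrit2, ")", call. = FALSE)
  }
  fit <- stats::lm(tt ~ photoperiod, data = obs)
  slope <- unname(stats::coef(fit)[2])
  base <- unname(stats::coef(fit)[1]) + slope * ppcrit1
  list(slope = slope, base = base, n_used = nrow(obs), fit = fit)
}

#' @export
print.cultivar_params <- function(x, ...) {
  cat("Cultivar '", x$name, "': Ppcrit ", x$ppcrit1, "-", x$ppcrit2,
      " h, Ppslope ", x$ppslope, " degCd/h, flower->maturity ",
      x$tt_flower_to_maturity, " degCd\n", sep = "")
  invisible(x)
}

#' @export
print.phenology_state <- function(x, ...) {
  cat("Phenology (", x$cultivar, "): stage ", x$stage, ", ",
      format(round(x$cum_tt, 1)), " degCd since sowing\n", sep = "")
  invisible(x)
}
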