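# Daily-timestep season simulator: couples weather, the soil water bucket,
# the phenology stage machine and the individual-leaf-area canopy into the
# crop water supply/demand (S/D) trajectory and final grain/biomass yields.

#' Simulation control parameters
#'
#' Tunable physiological and numerical constants of the simulator. Defaults
#' are conventional sorghum values: radiation use efficiency 1.25 g MJ-1,
#' light extinction 0.4, transpiration-efficiency coefficient 9 Pa, VPD
#' estimated as 0.75 of the saturation vapour pressure span, roots descending
#' 25 mm per day from a 100 mm sowing depth until flowering, post-flowering
#' senescence of 0.05% of leaf area per degree-day (tripled under severe
#' stress, S/D < 0.3), and up to 20% of the stem biomass present at the start
#' of grain filling available for retranslocation to grain.
#'
#' @param rue Radiation use efficiency, g biomass per MJ intercepted.
#' @param k Canopy light extinction coefficient.
#' @param te_coeff Transpiration-efficiency coefficient, Pa.
#' @param vpd_frac Fraction of the SVP span realized as daytime VPD.
#' @param root_rate Root descent, mm d-1 (sowing to flowering).
#' @param root_init Root depth at sowing, mm.
#' @param sen_rate Fractional leaf-area senescence per degree-day after
#'   flowering.
#' @param sen_mult Senescence multiplier under severe stress.
#' @param sen_thresh S/D threshold defining severe stress.
#' @param retrans_frac Fraction of the stem biomass present at the start of
#'   grain filling that can be retranslocated to grain, released uniformly
#'   over the fill period.
#' @param stem_frac Stem share of shoot biomass at the start of grain fill
#'   (used to estimate the retranslocatable stem pool; organs are not
#'   simulated separately).
#' @param grain_window Half-width (degree-days) of the anthesis window that
#'   sets grain number.
#' @param reset_fraction Fractional available soil water at the seasonal
#'   reset.
#' @param reset_day Day-of-year of the seasonal soil reset.
#' @param drainage_coef Daily fraction of above-DUL water draining.
#' @param x0_frac Relative rank of the largest leaf in the canopy profile.
#' @param water_limited If \code{FALSE}, supply always meets demand
#'   (potential production run).
#' @return A \code{sim_control} list.
#' @export
sim_control <- function(rue = 1.25, k = 0.4, te_coeff = 9, vpd_frac = 0.75,
                        root_rate = 25, root_init = 100, sen_rate = 5e-4,
                        sen_mult = 3, sen_thresh = 0.3, retrans_frac = 0.2,
                        stem_frac = 0.55, grain_window = 100, reset_fraction = 0.2,
                        reset_day = 121, drainage_coef = 0.5, x0_frac = 0.66,
                        water_limited = TRUE) {
  structure(as.list(environment()), class = "sim_control")
}

# smallest leaf number for which the largest-leaf regression is positive
min_profile_leaves <- function(cultivar) {
  max(cultivar$embryo_leaves,
      as.integer(floor(-cultivar$amax_intercept / cultivar$amax_slope)) + 1L)
}

#' Simulate one sorghum season
#'
#' Runs the full daily loop for one site-season: seasonal soil reset to 20%
#' fractional available water, rainfall-triggered sowing inside the window,
#' thermal-time phenology with the photoperiod-extended juvenile phase,
#' leaf-by-leaf canopy construction, radiation- and water-limited biomass
#' accumulation, the daily supply/demand stress index, and grain filling to
#' maturity.
#'
#' @param weather A \code{daily_weather} season (full calendar year).
#' @param cultivar A \code{\link{cultivar}}.
#' @param soil A \code{\link{soil_profile}} (see \code{\link{soil_preset}}).
#' @param management A \code{\link{management_spec}}.
#' @param control A \code{\link{sim_control}}.
#' @param sowing_doy Force sowing on this day instead of applying the
#'   rainfall trigger rule (used for sowing-date experiments).
#' @return An object of class \code{sorghum_season}: list with \code{daily}
#'   (per-day data.frame: doy, stage, tt, cum_tt, photoperiod, rain, supply,
#'   demand, sd_ratio, lai, biomass, grain, root_depth), \code{summary}
#'   (sowing/flowering/maturity days and degree-days, max leaf number, peak
#'   LAI, yields in kg ha-1, completion flags) and the inputs.
#' @examples
#' s <- site_spec("Samanko", 12.5, "800-1000", 920)
#' w <- generate_season(s, seed = 1)
#' run <- grow_season(w, cultivar("CSM63E"), soil_preset("high_swhc"))
#' summary(run)
#' @export
grow_season <- function(weather, cultivar, soil,
                        management = management_spec(),
                        control = sim_control(), sowing_doy = NULL) {
  stopifnot(inherits(weather, "daily_weather"),
            inherits(cultivar, "cultivar_params"),
            inherits(soil, "soil_profile"))

  state <- reset_fractional_asw(soil, control$reset_fraction)
  if (is.null(sowing_doy)) {
    sow <- sowing_date(weather, state,
                       window_start = management$sowing_window[1],
                       window_end = management$sowing_window[2],
                       start_doy = control$reset_day,
                       drainage_coef = control$drainage_coef)
    sowing_doy <- sow$doy
    state <- sow$state
    forced <- sow$forced
  } else {
    # walk the fallow balance up to the forced sowing day
    for (d in control$reset_day:(sowing_doy - 1L)) {
      i <- match(d, weather$doy)
      pe <- potential_soil_evap(state, weather$radn[i], 0)
      state <- step_water_balance(state, weather$rain[i], pe, 0,
                                  drainage_coef = control$drainage_coef)
    }
    forced <- FALSE
  }

  phen <- phenology_init(cultivar, sowing_doy)
  ndays <- max(weather$doy)
  days <- sowing_doy:ndays
  n <- length(days)

  rec <- data.frame(
    doy = days, stage = NA_character_, tt = 0, cum_tt = 0, photoperiod = 0,
    rain = 0, supply = 0, demand = 0, sd_ratio = 1, lai = 0, biomass = 0,
    grain = 0, root_depth = 0, stringsAsFactors = FALSE
  )

  min_leaves <- min_profile_leaves(cultivar)
  profile <- NULL
  profile_n <- -1L
  biomass <- 0           # g m-2
  grain <- 0             # g m-2
  sen_lai <- 0
  peak_lai <- 0
  lai_prev <- 0
  root_depth <- control$root_init
  window_growth <- 0
  window_days <- 0L
  grain_number <- NA_real_   # grains m-2
  grain_final <- FALSE
  retrans_pool <- NA_real_

  stage_num <- function(s) match(s, PHENO_STAGES)

  for (j in seq_len(n)) {
    d <- days[j]
    i <- match(d, weather$doy)
    tt <- daily_thermal_time(weather$tmax[i], weather$tmin[i], cultivar)
    pp <- weather$photoperiod[i]
    phen <- advance_phenology(phen, tt, pp, cultivar, doy = d)
    stg <- stage_num(phen$stage)

    # roots descend until flowering
    if (stg < stage_num("flowering")) {
      root_depth <- min(soil$total_depth,
                        control$root_init + control$root_rate * (j - 1L))
    }

    # canopy: leaf number fixed at panicle initiation, provisional before
    if (!is.na(phen$max_leaf_no)) {
      lea_no <- phen$max_leaf_no
    } else {
      tt_em <- max(0, phen$cum_tt - cultivar$tt_sow_to_emergence)
      lea_no <- total_leaf_number(tt_em, cultivar)
    }
    lea_no <- max(lea_no, min_leaves)
    if (lea_no != profile_n) {
      profile <- build_canopy_profile(lea_no, cultivar,
                                      x0_frac = control$x0_frac)
      profile_n <- lea_no
    }
    leaves_emerged <- if (stg >= stage_num("emergence")) {
      min(lea_no, cultivar$embryo_leaves +
            max(0, phen$cum_tt - cultivar$tt_sow_to_emergence) /
            cultivar$phyllochron)
    } else 0
    lai_pot <- canopy_lai(profile, leaves_emerged, management$plant_density)
    lai <- max(0, lai_pot - sen_lai)

    # rain and surface evaporation first, then uptake against the wetted state
    pe <- potential_soil_evap(state, weather$radn[i], lai)
    state <- step_water_balance(state, weather$rain[i], pe, 0,
                                drainage_coef = control$drainage_coef)

    growing <- stg >= stage_num("emergence") && stg < stage_num("maturity")
    pot_growth <- if (growing) {
      control$rue * radiation_interception(weather$radn[i], lai_prev, control$k)
    } else 0
    vpd <- vpd_estimate(weather$tmax[i], weather$tmin[i], control$vpd_frac)
    demand <- transpiration_demand(pot_growth, vpd, control$te_coeff)
    soil_supply <- water_supply(state, root_depth)
    supply <- if (control$water_limited) soil_supply else demand
    sdr <- sd_ratio(supply, demand)
    uptake <- min(demand, soil_supply)
    growth <- pot_growth * min(1, if (demand > 0) supply / demand else 1)
    state <- take_uptake(state, uptake)

    biomass <- biomass + growth

    # grain number from mean growth rate over the anthesis window
    t_flower <- unname(phen$targets["flowering"])
    if (!is.na(t_flower) && stg >= stage_num("flag_leaf")) {
      dist <- phen$cum_tt - t_flower
      if (abs(dist) <= control$grain_window) {
        window_growth <- window_growth + growth
        window_days <- window_days + 1L
      } else if (dist > control$grain_window) grain_final <- TRUE
    }
    if (!is.na(t_flower) && window_days > 0) {
      grain_number <- (window_growth / window_days) / cultivar$dm_per_seed
    }

    # grain filling between start of grain fill and maturity
    if (stg >= stage_num("start_grain_fill") && stg < stage_num("maturity") &&
        !is.na(grain_number)) {
      if (is.na(retrans_pool)) {
        retrans_pool <- control$retrans_frac * control$stem_frac * biomass
      }
      gdemand <- cultivar$max_gf_rate / 1000 * grain_number * tt  # mg -> g
      from_assim <- min(gdemand, growth)
      # stem reserves released uniformly over the remaining fill duration
      t_mat <- unname(phen$targets["maturity"])
      remaining_tt <- max(t_mat - (phen$cum_tt - tt), tt)
      release_cap <- retrans_pool * min(1, tt / remaining_tt)
      from_retrans <- min(release_cap, max(0, gdemand - from_assim))
      grain <- grain + from_assim + from_retrans
      retrans_pool <- retrans_pool - from_retrans
    }

    # post-flowering senescence
    if (stg >= stage_num("flowering")) {
      rate <- control$sen_rate * (if (sdr < control$sen_thresh) control$sen_mult else 1)
      sen_lai <- min(lai_pot, sen_lai + lai * rate * tt)
    }

    peak_lai <- max(peak_lai, lai)
    lai_prev <- lai
    rec$stage[j] <- phen$stage
    rec$tt[j] <- tt; rec$cum_tt[j] <- phen$cum_tt; rec$photoperiod[j] <- pp
    rec$rain[j] <- weather$rain[i]
    rec$supply[j] <- supply; rec$demand[j] <- demand; rec$sd_ratio[j] <- sdr
    rec$lai[j] <- lai; rec$biomass[j] <- biomass; rec$grain[j] <- grain
    rec$root_depth[j] <- root_depth

    if (phen$stage == "ripe") { rec <- rec[seq_len(j), ]; break }
  }

  tr_tt <- phen$transition_tt
  tr_doy <- phen$transition_doy
  pick <- function(v, s) if (s %in% names(v)) unname(v[s]) else NA_real_
  summ <- list(
    site = attr(weather, "site"), cultivar = cultivar$name, soil = soil$name,
    sowing_doy = sowing_doy, forced_sowing = forced,
    flowering_doy = pick(tr_doy, "flowering"),
    maturity_doy = pick(tr_doy, "maturity"),
    flowering_tt = pick(tr_tt, "flowering"),
    maturity_tt = pick(tr_tt, "maturity"),
    flower_to_maturity_tt = pick(tr_tt, "maturity") - pick(tr_tt, "flowering"),
    max_leaf_no = phen$max_leaf_no,
    peak_lai = peak_lai,
    biomass_kg_ha = biomass * 10,      # g m-2 -> kg ha-1
    grain_kg_ha = grain * 10,
    grain_number_m2 = grain_number,
    matured = !is.na(pick(tr_doy, "maturity")),
    final_stage = phen$stage
  )

  structure(
    list(daily = rec, summary = summ, phenology = phen,
         cultivar = cultivar, soil = soil, management = management,
         control = control),
    class = "sorghum_season"
  )
}

#' @export
print.sorghum_season <- function(x, ...) {
  s <- x$summary
  cat("Sorghum season: ", s$cultivar, " on ", s$soil, " at ", s$site, "\n",
      sep = "")
  cat("  sown doy ", s$sowing_doy, if (isTRUE(s$forced_sowing)) " (forced)",
      ", flowering doy ", s$flowering_doy, ", maturity doy ", s$maturity_doy,
      "\n", sep = "")
  cat("  leaves ", s$max_leaf_no, ", peak LAI ", round(s$peak_lai, 2),
      ", biomass ", round(s$biomass_kg_ha), " kg/ha, grain ",
      round(s$grain_kg_ha), " kg/ha\n", sep = "")
  invisible(x)
}

#' @export
summary.sorghum_season <- function(object, ...) {
  out <- object$summary
  class(out) <- "summary.sorghum_season"
  out
}

#' @export
print.summary.sorghum_season <- function(x, ...) {
  df <- data.frame(value = unlist(lapply(x, function(v)
    if (is.numeric(v)) round(v, 3) else v)))
  print(df)
  invisible(x)
}

#' @export
plot.sorghum_season <- function(x, ...) {
  d <- x$daily
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(d$doy, d$sd_ratio, type = "l", ylim = c(0, 1.05),
                 xlab = "", ylab = "S/D ratio", ...)
  fl <- x$summary$flowering_doy
  if (!is.na(fl)) graphics::abline(v = fl, lty = 2)
  graphics::plot(d$doy, d$lai, type = "l", xlab = "", ylab = "LAI")
  if (!is.na(fl)) graphics::abline(v = fl, lty = 2)
  graphics::plot(d$doy, d$biomass * 10, type = "l", xlab = "day of year",
                 ylab = "biomass (kg/ha)")
  graphics::lines(d$doy, d$grain * 10, lty = 3)
  invisible(x)
}

#' Daily output of a simulated season as a data.frame
#'
#' @param run A \code{sorghum_season}.
#' @return The per-day record with run identifiers prepended.
#' @export
season_daily <- function(run) {
  stopifnot(inherits(run, "sorghum_season"))
  cbind(site = run$summary$site, cultivar = run$summary$cultivar,
        soil = run$summary$soil, run$daily, stringsAsFactors = FALSE)
}
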