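# Layered bucket soil-water balance.
#
# Water cascades down the profile: rain infiltrates the surface layer, any
# storage above the drained upper limit drains to the layer below at a daily
# drainage coefficient, and drainage out of the deepest layer is lost. Soil
# evaporation acts on the surface layer only (two-stage: energy-limited, then
# falling-rate); root uptake is distributed over layers in proportion to the
# kl-weighted available water. Mass balance closes to machine precision by
# construction.

#' Define a layered soil profile
#'
#' @param layer_thickness Numeric vector of layer thicknesses (mm).
#' @param ll,dul,sat Volumetric lower limit, drained upper limit and
#'   saturation per layer; must satisfy \code{ll < dul < sat}.
#' @param kl Per-layer daily fraction of available water extractable by roots.
#' @param organic_carbon Percent organic carbon (metadata).
#' @param name Profile name.
#' @return An object of class \code{soil_profile} with derived \code{swhc}
#'   (mm plant-available water) and \code{total_depth} (mm).
#' @examples
#' soil_preset("low_swhc")$swhc   # 62 mm
#' @export
soil_profile <- function(layer_thickness, ll, dul, sat, kl = 0.07,
                         organic_carbon = NA_real_, name = "custom") {
  n <- length(layer_thickness)
  ll <- rep_len(ll, n); dul <- rep_len(dul, n); sat <- rep_len(sat, n)
  kl <- rep_len(kl, n)
  if (any(layer_thickness <= 0)) stop("layer thicknesses must be positive", call. = FALSE)
  if (any(!(ll < dul & dul < sat))) {
    stop("each layer must satisfy LL < DUL < SAT", call. = FALSE)
  }
  if (any(kl < 0 | kl > 1)) stop("kl must lie in [0, 1]", call. = FALSE)
  structure(
    list(name = name, layer_thickness = layer_thickness, ll = ll, dul = dul,
         sat = sat, kl = kl, organic_carbon = organic_carbon,
         swhc = sum((dul - ll) * layer_thickness),
         total_depth = sum(layer_thickness)),
    class = "soil_profile"
  )
}

#' Bundled soil presets
#'
#' Two profiles representing the main Malian sorghum soils: a shallow
#' Plinthaquic Kandustalf holding 62 mm of plant-available water over 1010 mm
#' (\code{"low_swhc"}, 0.2% organic carbon) and a deeper Alfisol holding
#' 156 mm over 1200 mm (\code{"high_swhc"}, 0.37% organic carbon). Layers are
#' uniform in (DUL - LL) so the stated water holding capacities are reproduced
#' exactly; kl is 0.07 per day throughout.
#'
#' @param name \code{"low_swhc"} or \code{"high_swhc"}.
#' @return A \code{\link{soil_profile}}.
#' @export
soil_preset <- function(name = c("low_swhc", "high_swhc")) {
  name <- match.arg(name)
  if (name == "low_swhc") {
    thick <- c(150, 150, 180, 180, 180, 170)  # 1010 mm
    d <- 62 / 1010
    soil_profile(thick, ll = 0.10, dul = 0.10 + d, sat = 0.10 + d + 0.08,
                 kl = 0.07, organic_carbon = 0.2, name = name)
  } else {
    thick <- c(150, 150, 180, 180, 180, 180, 180)  # 1200 mm
    d <- 156 / 1200
    soil_profile(thick, ll = 0.12, dul = 0.12 + d, sat = 0.12 + d + 0.08,
                 kl = 0.07, organic_carbon = 0.37, name = name)
  }
}

new_soil_state <- function(profile, sw) {
  structure(
    list(profile = profile, sw = sw,
         cum = c(rain_in = 0, drainage = 0, soil_evap = 0, transpiration = 0),
         evap_since_wet = 0),
    class = "soil_water_state"
  )
}

#' Reset the profile to a fraction of its available water capacity
#'
#' Plant-available water is set to \code{fraction * SWHC}, filled top-down
#' (surface layers reach DUL before deeper layers receive any water), which
#' mimics a profile wetted by early-season rains.
#'
#' @param profile A \code{\link{soil_profile}}.
#' @param fraction Fraction of SWHC in [0, 1]; seasonal resets use 0.2.
#' @return A \code{soil_water_state}.
#' @examples
#' st <- reset_fractional_asw(soil_preset("high_swhc"), 0.2)
#' available_soil_water(st)  # 31.2 mm
#' @export
reset_fractional_asw <- function(profile, fraction) {
  stopifnot(inherits(profile, "soil_profile"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  cap <- (profile$dul - profile$ll) * profile$layer_thickness
  remaining <- fraction * profile$swhc
  fill <- numeric(length(cap))
  for (i in seq_along(cap)) {
    fill[i] <- min(remaining, cap[i])
    remaining <- remaining - fill[i]
  }
  new_soil_state(profile, profile$ll * profile$layer_thickness + fill)
}

#' Plant-available water currently stored (mm)
#'
#' @param state A \code{soil_water_state}.
#' @return Total water above the lower limit, mm.
#' @export
available_soil_water <- function(state) {
  sum(state$sw - state$profile$ll * state$profile$layer_thickness)
}

#' Advance the soil water balance by one day
#'
#' Root uptake is extracted first, against the same morning state on which
#' \code{\link{water_supply}} is evaluated (distributed over layers in
#' proportion to kl-weighted available water, never pushing a layer below
#' LL). Rain then infiltrates the top layer (no runoff); storage above DUL
#' cascades to the next layer at the drainage coefficient per day and is lost
#' below the profile; soil evaporation is taken from the top layer only,
#' capped by its available water.
#'
#' @param state A \code{soil_water_state}.
#' @param rain Rain (mm), >= 0.
#' @param potential_soil_evap Potential surface evaporation (mm), >= 0.
#' @param transpiration_uptake Crop uptake (mm), >= 0; must not exceed the
#'   kl-limited supply of the whole profile (callers should respect
#'   \code{\link{water_supply}}).
#' @param drainage_coef Fraction of above-DUL water draining per day.
#' @return The updated \code{soil_water_state}; cumulative fluxes are tracked
#'   in \code{state$cum}.
#' @export
step_water_balance <- function(state, rain, potential_soil_evap = 0,
                               transpiration_uptake = 0, drainage_coef = 0.5) {
  stopifnot(inherits(state, "soil_water_state"))
  if (rain < 0 || potential_soil_evap < 0 || transpiration_uptake < 0) {
    stop("fluxes must be non-negative", call. = FALSE)
  }
  p <- state$profile
  sw <- state$sw
  llv <- p$ll * p$layer_thickness
  dulv <- p$dul * p$layer_thickness
  satv <- p$sat * p$layer_thickness

  # root uptake against the morning state, proportional to kl * available
  avail <- pmax(0, sw - llv)
  supply_l <- p$kl * avail
  total_supply <- sum(supply_l)
  if (transpiration_uptake > total_supply + 1e-9) {
    stop("requested uptake (", format(transpiration_uptake),
         " mm) exceeds available supply (", format(total_supply), " mm)",
         call. = FALSE)
  }
  if (transpiration_uptake > 0 && total_supply > 0) {
    sw <- sw - transpiration_uptake * supply_l / total_supply
  }

  # infiltration + cascade
  inflow <- rain
  for (i in seq_along(sw)) {
    sw[i] <- sw[i] + inflow
    over_sat <- max(0, sw[i] - satv[i])        # instantaneous overflow
    drain <- over_sat + drainage_coef * max(0, sw[i] - over_sat - dulv[i])
    sw[i] <- sw[i] - drain
    inflow <- drain
  }
  lost <- inflow

  # surface evaporation, capped by water above LL in the top layer
  evap <- min(potential_soil_evap, max(0, sw[1] - llv[1]))
  sw[1] <- sw[1] - evap

  state$sw <- sw
  state$cum["rain_in"] <- state$cum["rain_in"] + rain
  state$cum["drainage"] <- state$cum["drainage"] + lost
  state$cum["soil_evap"] <- state$cum["soil_evap"] + evap
  state$cum["transpiration"] <- state$cum["transpiration"] + transpiration_uptake
  # two-stage evaporation bookkeeping: rain rewets the surface
  state$evap_since_wet <- max(0, state$evap_since_wet + evap - rain)
  state
}

# Remove root uptake only (no rain/drainage/evap), kl-distributed over layers.
# Used by the simulator after the day's cascade so supply and extraction see
# the same state.
take_uptake <- function(state, uptake) {
  if (uptake <= 0) return(state)
  p <- state$profile
  avail <- pmax(0, state$sw - p$ll * p$layer_thickness)
  supply_l <- p$kl * avail
  total <- sum(supply_l)
  if (uptake > total + 1e-9) {
    stop("requested uptake (", format(uptake),
         " mm) exceeds available supply (", format(total), " mm)", call. = FALSE)
  }
  state$sw <- state$sw - uptake * supply_l / total
  state$cum["transpiration"] <- state$cum["transpiration"] + uptake
  state
}

#' Potential daily soil evaporation (two-stage)
#'
#' Stage 1 (energy-limited) until cumulative evaporation since the last
#' wetting reaches \code{u_stage1}; thereafter a square-root-of-time falling
#' rate. The energy-limited rate declines with canopy shading.
#'
#' @param state A \code{soil_water_state} (carries the since-wetting counter).
#' @param radn Solar radiation, MJ m-2 d-1.
#' @param lai Canopy leaf area index shading the surface.
#' @param u_stage1 Stage-1 cumulative limit (mm); 6 is typical for loams.
#' @param alpha Stage-2 coefficient (mm d^-0.5).
#' @return Potential evaporation, mm d-1.
#' @export
potential_soil_evap <- function(state, radn, lai = 0, u_stage1 = 6, alpha = 3.5) {
  eos <- max(0, (0.4 + 0.08 * radn)) * exp(-0.4 * lai)
  cum <- state$evap_since_wet
  if (cum < u_stage1) return(eos)
  t2 <- ((cum - u_stage1) / alpha)^2
  min(eos, alpha * (sqrt(t2 + 1) - sqrt(t2)))
}

#' Daily root water supply
#'
#' Supply is the kl-weighted available water summed over rooted layers, with
#' the deepest rooted layer included in proportion to root penetration.
#'
#' @param state A \code{soil_water_state}.
#' @param root_depth Rooting depth, mm, >= 0.
#' @return Potential daily uptake, mm d-1.
#' @examples
#' st <- reset_fractional_asw(soil_preset("low_swhc"), 1)
#' water_supply(st, 500)
#' @export
water_supply <- function(state, root_depth) {
  stopifnot(inherits(state, "soil_water_state"))
  if (root_depth < 0) stop("root_depth must be >= 0", call. = FALSE)
  p <- state$profile
  llv <- p$ll * p$layer_thickness
  bottom <- cumsum(p$layer_thickness)
  top <- c(0, bottom[-length(bottom)])
  frac <- pmin(1, pmax(0, (root_depth - top) / p$layer_thickness))
  sum(p$kl * pmax(0, state$sw - llv) * frac)
}

#' @export
print.soil_profile <- function(x, ...) {
  cat("Soil profile '", x$name, "': ", length(x$layer_thickness), " layers, ",
      format(x$total_depth), " mm deep, SWHC ", format(round(x$swhc, 2)),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.soil_water_state <- function(x, ...) {
  cat("Soil water state (", x$profile$name, "): available water ",
      format(round(available_soil_water(x), 2)), " mm of ",
      format(round(x$profile$swhc, 2)), " mm SWHC\n", sep = "")
  cat("Cumulative fluxes (mm): ",
      paste(names(x$cum), round(x$cum, 2), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
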