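# Individual-leaf-area (ILA) canopy and water-limited growth.
#
# Canopy size is assembled leaf by leaf: the area of each main-stem leaf
# follows a bell-shaped profile over leaf rank, the largest leaf scales
# linearly with the total leaf number, and the total leaf number is itself set
# by the photoperiod-dependent duration of the juvenile phase. This is the
# mechanistic loop that makes photoperiod-sensitive cultivars build larger
# canopies when sown early: longer days -> later panicle initiation -> more
# leaves -> larger leaves and leaf area -> more transpiration demand.

#' Area of an individual leaf from the bell-shaped rank profile
#'
#' \code{Y = Y0 * exp(a * (X - X0)^2 + b * (X - X0)^3)}, where X is the leaf
#' rank, X0 the rank of the largest leaf, Y0 its area, \code{a < 0} the
#' breadth and \code{b} the skewness of the bell.
#'
#' @param X Leaf rank (1..MaxLNo), vectorized.
#' @param params A \code{leaf_profile} from \code{\link{build_canopy_profile}},
#'   or any list with \code{x0}, \code{y0}, \code{a}, \code{b}.
#' @return Leaf area, cm2.
#' @export
individual_leaf_area <- function(X, params) {
  d <- X - params$x0
  params$y0 * exp(params$a * d^2 + params$b * d^3)
}

#' Area of the largest main-stem leaf
#'
#' Linear regression of largest-leaf area on total leaf number:
#' \code{Y0 = MaxLNo * aMaxSlope + aMaxIntercept}.
#'
#' @param max_leaf_no Total main-stem leaf number.
#' @param cultivar A \code{\link{cultivar}} (supplies slope and intercept).
#' @return Area, cm2 (> 0).
#' @examples
#' largest_leaf_area(20, cultivar("CSM63E"))  # 271.906 cm2
#' @export
largest_leaf_area <- function(max_leaf_no, cultivar) {
  y0 <- max_leaf_no * cultivar$amax_slope + cultivar$amax_intercept
  if (any(y0 <= 0)) {
    stop("leaf number ", paste(max_leaf_no[y0 <= 0], collapse = ", "),
         " is below the domain of the largest-leaf regression (Y0 <= 0)",
         call. = FALSE)
  }
  y0
}

#' Build the full per-leaf canopy profile
#'
#' Places the largest leaf at \code{x0_frac * MaxLNo}, derives its area from
#' the largest-leaf regression scaled by the cultivar's largest-leaf
#' multiplier (converting the main-culm regression to an effective per-plant
#' area), and evaluates the bell profile at every rank. The breadth and
#' skewness coefficients default to simple functions of leaf number
#' (\code{a = -0.009 - 0.2 / MaxLNo}, \code{b = 0.0006}); the source
#' regressions for these are not published, so both are exposed as arguments.
#'
#' @param max_leaf_no Total main-stem leaf number (>= embryonic leaves).
#' @param cultivar A \code{\link{cultivar}}.
#' @param x0_frac Relative rank of the largest leaf.
#' @param a,b Breadth (< 0) and skewness constants; \code{NULL} uses the
#'   leaf-number defaults.
#' @return An object of class \code{leaf_profile}: list with \code{x0},
#'   \code{y0}, \code{a}, \code{b}, \code{max_leaf_no} and \code{leaf_area}
#'   (cm2 per rank).
#' @examples
#' p <- build_canopy_profile(20, cultivar("CSM63E"))
#' sum(p$leaf_area)   # total plant leaf area, cm2
#' @export
build_canopy_profile <- function(max_leaf_no, cultivar, x0_frac = 0.66,
                                 a = NULL, b = NULL) {
  if (max_leaf_no < cultivar$embryo_leaves) {
    stop("max_leaf_no must be >= the embryonic leaf number", call. = FALSE)
  }
  if (is.null(a)) a <- -0.009 - 0.2 / max_leaf_no
  if (is.null(b)) b <- 0.0006
  if (a >= 0) stop("breadth constant a must be negative", call. = FALSE)
  y0 <- largest_leaf_area(max_leaf_no, cultivar) * cultivar$largest_leaf_multiplier
  params <- structure(
    list(max_leaf_no = as.integer(max_leaf_no), x0 = x0_frac * max_leaf_no,
         y0 = y0, a = a, b = b),
    class = "leaf_profile"
  )
  params$leaf_area <- individual_leaf_area(seq_len(max_leaf_no), params)
  params
}

#' Leaf area index from emerged leaves
#'
#' Sums the profile areas of the emerged leaves (fractional emergence of the
#' youngest leaf included pro rata) and converts to ground area basis.
#'
#' @param profile A \code{leaf_profile}.
#' @param leaves_emerged Number of emerged leaves (may be fractional).
#' @param plant_density Plants per m2.
#' @return LAI, m2 leaf per m2 ground.
#' @export
canopy_lai <- function(profile, leaves_emerged, plant_density) {
  n <- max(0, min(leaves_emerged, profile$max_leaf_no))
  full <- floor(n)
  area <- if (full > 0) sum(profile$leaf_area[seq_len(full)]) else 0
  if (full < profile$max_leaf_no && n > full) {
    area <- area + (n - full) * profile$leaf_area[full + 1L]
  }
  area / 1e4 * plant_density
}

#' Vapour pressure deficit estimated from the temperature range
#'
#' @param tmax,tmin Daily extremes, deg C.
#' @param frac Fraction of the saturation vapour pressure span realized as
#'   daytime deficit.
#' @return VPD, kPa (floored at a small positive value).
#' @export
vpd_estimate <- function(tmax, tmin, frac = 0.75) {
  pmax(frac * (svp(tmax) - svp(tmin)), 0.01)
}

#' Daily transpiration demand
#'
#' Demand is the water needed to realize the day's potential (radiation-
#' limited) biomass gain at the current vapour pressure deficit:
#' \code{demand = growth * vpd / TE}, with the transpiration-efficiency
#' coefficient in Pa so that, e.g., 9 Pa at 2 kPa VPD gives 4.5 g biomass per
#' m2 per mm of water.
#'
#' @param potential_biomass_gain g m-2 d-1.
#' @param vpd kPa, > 0.
#' @param te_coeff Transpiration-efficiency coefficient, Pa.
#' @return Demand, mm d-1.
#' @export
transpiration_demand <- function(potential_biomass_gain, vpd, te_coeff = 9) {
  if (any(vpd <= 0)) stop("vpd must be positive", call. = FALSE)
  pmax(0, potential_biomass_gain) * vpd / te_coeff
}

#' Crop water supply/demand stress index
#'
#' \code{min(1, supply / demand)}, defined as 1 when demand is zero (no
#' transpiring canopy implies no stress) and floored at 1e-6 so the index
#' stays strictly positive on a fully dried root zone.
#'
#' @param supply,demand mm d-1, >= 0.
#' @return Index in (0, 1], vectorized.
#' @export
sd_ratio <- function(supply, demand) {
  if (any(supply < 0) || any(demand < 0)) {
    stop("supply and demand must be non-negative", call. = FALSE)
  }
  out <- ifelse(demand <= 0, 1, pmin(1, supply / demand))
  pmax(out, 1e-6)
}

#' Intercepted radiation
#'
#' Beer's law canopy light interception.
#'
#' @param radn Incident solar radiation, MJ m-2 d-1.
#' @param lai Leaf area index.
#' @param k Extinction coefficient.
#' @return Intercepted radiation, MJ m-2 d-1.
#' @export
radiation_interception <- function(radn, lai, k = 0.4) {
  radn * (1 - exp(-k * lai))
}

#' Management settings
#'
#' @param plant_density Plants per m2 (farmer practice default 5.7).
#' @param row_spacing Row spacing, cm (86).
#' @param sowing_window Day-of-year bounds of the sowing window
#'   (June 1 to July 15).
#' @return A \code{management_spec} list.
#' @export
management_spec <- function(plant_density = 5.7, row_spacing = 86,
                            sowing_window = c(152, 196)) {
  if (plant_density <= 0) stop("plant_density must be positive", call. = FALSE)
  structure(list(plant_density = plant_density, row_spacing = row_spacing,
                 sowing_window = sowing_window),
            class = "management_spec")
}
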