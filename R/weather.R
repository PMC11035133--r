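# Synthetic monsoonal weather for the Malian sorghum belt.
#
# The generator is a WGEN-style emulator: a first-order two-state Markov chain
# for wet/dry days whose wet-day probability follows a within-season profile
# between a stochastic onset (high variance) and cessation (low variance),
# gamma-distributed wet-day amounts scaled so the expected annual total matches
# the site target, and sinusoidal temperature/radiation cycles with noise.

#' Isohyet zone climatology
#'
#' Climatological constants per isohyet zone: default annual rainfall target
#' (mm), mean onset and cessation day-of-year of the rains (onset is later and
#' the season shorter toward the drier north), and the nominal wet window used
#' by the seasonality checks. Onset standard deviation is 12 d, cessation 5 d,
#' reflecting the much more variable start than end of the Sahelian rainy
#' season.
#'
#' @return A data.frame with one row per zone.
#' @export
isohyet_zones <- function() {
  data.frame(
    zone        = c("400-600", "600-800", "800-1000", ">1000"),
    target_rain = c(500, 700, 900, 1100),
    onset_mean  = c(176, 170, 163, 156),
    cess_mean   = c(278, 283, 288, 293),
    onset_sd    = 12,
    cess_sd     = 5,
    window_start = 140,
    window_end   = 310,
    stringsAsFactors = FALSE
  )
}

#' Reference site table
#'
#' The 18 weather stations spanning the North-South rainfall gradient of Mali
#' (Sahelian through pre-Guinean zones), with their isohyet class, latitude,
#' number of recorded seasons and mean annual rainfall. Used as calibration
#' metadata for the synthetic generator; the station records themselves are not
#' distributed.
#'
#' @return A data.frame with columns \code{site}, \code{isohyet},
#'   \code{longitude}, \code{latitude}, \code{n_seasons},
#'   \code{mean_rainfall}.
#' @export
mali_sites <- function() {
  data.frame(
    site = c("Nara", "Mopti", "Kayes", "Segou", "Cinzana", "Tominian",
             "Kolokani", "Dioila", "Samanko", "Koutiala", "Sotuba", "Massigui",
             "Kita", "Kangaba", "Fakola", "Kenieba", "Bougouni", "Sikasso"),
    isohyet = c("400-600", "400-600", "600-800", "600-800", "600-800",
                "600-800", "600-800", "800-1000", "800-1000", "800-1000",
                "800-1000", "800-1000", "800-1000", ">1000", ">1000", ">1000",
                ">1000", ">1000"),
    longitude = c(-7.3, -4.1, -11.4, -6.2, -5.9, -4.6, -8.0, -6.8, -8.1, -5.5,
                  -7.9, -6.8, -9.5, -8.4, -6.9, -11.4, -7.5, -5.7),
    latitude = c(15.2, 14.5, 14.4, 13.4, 13.3, 13.3, 13.6, 12.5, 12.5, 12.4,
                 12.7, 11.9, 13.1, 11.9, 10.5, 12.8, 11.4, 11.4),
    n_seasons = c(23, 25, 24, 28, 30, 10, 26, 28, 34, 58, 64, 30, 70, 26, 12,
                  17, 27, 30),
    mean_rainfall = c(426, 492, 651, 661, 697, 715, 753, 860, 920, 922, 942,
                      943, 986, 1040, 1054, 1159, 1161, 1170),
    stringsAsFactors = FALSE
  )
}

#' Site specifications for the full Malian network
#'
#' Builds \code{\link{site_spec}}s for all 18 reference stations, using each
#' station's latitude, isohyet class and mean annual rainfall as the
#' calibration target, and season counts proportional to the historical
#' record lengths (scaled by \code{seasons_scale}, minimum 2 per site).
#'
#' @param seasons_scale Multiplier on the historical season counts; 1 emulates
#'   the full 459-site-year record, smaller values give proportionally
#'   thinner ensembles.
#' @return Named list of \code{site_spec} objects.
#' @export
mali_site_specs <- function(seasons_scale = 1) {
  tab <- mali_sites()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    site_spec(tab$site[i], tab$latitude[i], tab$isohyet[i],
              target_annual_rainfall = tab$mean_rainfall[i],
              n_seasons = max(2L, round(tab$n_seasons[i] * seasons_scale)))
  })
  names(out) <- tab$site
  out
}

#' Define a simulation site
#'
#' @param name Site name.
#' @param latitude Degrees north, within [5, 20].
#' @param isohyet_zone One of \code{"400-600"}, \code{"600-800"},
#'   \code{"800-1000"}, \code{">1000"} (mm annual rainfall class).
#' @param target_annual_rainfall Mean annual rainfall target in mm; defaults to
#'   the zone climatology.
#' @param n_seasons Number of seasons to emulate for this site.
#' @return An object of class \code{site_spec}.
#' @examples
#' site_spec("Samanko", 12.5, "800-1000", target_annual_rainfall = 920)
#' @export
site_spec <- function(name, latitude, isohyet_zone,
                      target_annual_rainfall = NULL, n_seasons = 1L) {
  zones <- isohyet_zones()
  if (!isohyet_zone %in% zones$zone) {
    stop("unknown isohyet_zone '", isohyet_zone, "'; must be one of: ",
         paste(zones$zone, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(latitude) || latitude < 5 || latitude > 20) {
    stop("latitude must lie in [5, 20] degrees north", call. = FALSE)
  }
  zi <- zones[zones$zone == isohyet_zone, ]
  if (is.null(target_annual_rainfall)) target_annual_rainfall <- zi$target_rain
  if (target_annual_rainfall < 0) {
    stop("target_annual_rainfall must be non-negative", call. = FALSE)
  }
  if (n_seasons < 1) stop("n_seasons must be >= 1", call. = FALSE)
  structure(
    list(name = name, latitude = latitude, isohyet_zone = isohyet_zone,
         target_annual_rainfall = target_annual_rainfall,
         n_seasons = as.integer(n_seasons),
         onset_mean = zi$onset_mean, cess_mean = zi$cess_mean,
         onset_sd = zi$onset_sd, cess_sd = zi$cess_sd,
         window_start = zi$window_start, window_end = zi$window_end),
    class = "site_spec"
  )
}

# Deterministic small hash of a site so different sites diverge under one seed.
site_seed <- function(site, seed) {
  h <- sum(utf8ToInt(site$name) * seq_along(utf8ToInt(site$name))) +
    round(site$latitude * 97) + round(site$target_annual_rainfall)
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

# Evaluate a function with an isolated RNG stream, restoring the caller's.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Saturated vapour pressure (kPa) at temperature T (deg C), Tetens form.
svp <- function(temp) 0.6108 * exp(17.27 * temp / (temp + 237.3))

#' Day length including civil twilight
#'
#' Geometric day length from solar declination and hour angle, with the horizon
#' depressed by \code{twilight_angle} degrees so that twilight counts toward
#' the photoperiod perceived by the crop.
#'
#' @param latitude Degrees (positive north); absolute value must not exceed 60.
#' @param day_of_year Integer day of year, 1..366.
#' @param twilight_angle Degrees below the horizon at which daylight is deemed
#'   to end; 2.2 is the convention for crop photoperiodism, 0 gives geometric
#'   sunrise/sunset.
#' @return Day length in hours, in (0, 24).
#' @examples
#' daylength(12.5, 172)           # near-solstice photoperiod at Samanko
#' daylength(0, 80, twilight_angle = 0)  # 12 h at the equator
#' @export
daylength <- function(latitude, day_of_year, twilight_angle = 2.2) {
  if (any(abs(latitude) > 60)) {
    stop("unsupported latitude: |latitude| must be <= 60 degrees", call. = FALSE)
  }
  if (any(day_of_year < 1 | day_of_year > 366)) {
    stop("day_of_year must lie in 1..366", call. = FALSE)
  }
  rad <- pi / 180
  decl <- -23.45 * cos(2 * pi * (day_of_year + 10) / 365)
  cosw <- (sin(-twilight_angle * rad) -
             sin(latitude * rad) * sin(decl * rad)) /
    (cos(latitude * rad) * cos(decl * rad))
  if (any(cosw < -1 | cosw > 1)) {
    stop("polar day/night encountered; unsupported latitude/twilight combination",
         call. = FALSE)
  }
  2 * acos(cosw) / rad / 15
}

#' Generate one synthetic season of daily weather
#'
#' Produces a full 365-day calendar year of rainfall, temperature, radiation
#' and photoperiod for a site. Rainfall occurrence follows a first-order
#' two-state Markov chain whose marginal wet-day probability traces a
#' half-sine profile between a stochastic onset and cessation of the rains;
#' wet-day amounts are gamma distributed and scaled so the expected annual
#' total equals the site target. Temperatures and radiation are sinusoidal
#' annual cycles with Gaussian noise; wet days are cooler and 20% less sunny.
#'
#' Identical \code{(site, seed)} pairs yield identical series.
#'
#' @param site A \code{\link{site_spec}}.
#' @param seed Integer seed controlling all stochastic components.
#' @return A \code{daily_weather} data.frame with columns \code{year},
#'   \code{doy}, \code{rain} (mm), \code{tmax}, \code{tmin} (deg C),
#'   \code{radn} (MJ m-2 d-1) and \code{photoperiod} (h), plus \code{site} and
#'   \code{latitude} attributes.
#' @examples
#' s <- site_spec("Samanko", 12.5, "800-1000", 920)
#' w <- generate_season(s, seed = 42)
#' sum(w$rain)
#' @export
generate_season <- function(site, seed) {
  stopifnot(inherits(site, "site_spec"))
  with_seed(site_seed(site, seed), {
    ndays <- 365L
    doy <- seq_len(ndays)

    onset <- round(stats::rnorm(1, site$onset_mean, site$onset_sd))
    cess  <- round(stats::rnorm(1, site$cess_mean, site$cess_sd))
    onset <- min(max(onset, site$window_start), site$onset_mean + 25)
    cess  <- max(min(cess, site$window_end), site$cess_mean - 15)
    if (cess <= onset + 20) cess <- onset + 21

    # marginal wet-day probability: half-sine between onset and cessation
    p_peak <- 0.7
    pwet <- numeric(ndays)
    in_season <- doy >= onset & doy <= cess
    pwet[in_season] <- p_peak * sin(pi * (doy[in_season] - onset) / (cess - onset))

    # first-order chain with persistence r: p01 = (1-r)*pi, p11 = r + (1-r)*pi
    r <- 0.25
    wet <- logical(ndays)
    state <- FALSE
    u <- stats::runif(ndays)
    for (d in doy) {
      p <- if (state) r + (1 - r) * pwet[d] else (1 - r) * pwet[d]
      state <- u[d] < p
      wet[d] <- state
    }

    expected_wet <- sum(pwet)
    mean_amount <- if (expected_wet > 0) site$target_annual_rainfall / expected_wet else 0
    rain <- numeric(ndays)
    nwet <- sum(wet)
    if (nwet > 0 && mean_amount > 0) {
      rain[wet] <- stats::rgamma(nwet, shape = 1, scale = mean_amount)
    }

    tmin <- 21 + 2.0 * cos(2 * pi * (doy - 140) / 365) + stats::rnorm(ndays, 0, 1.0)
    tmax <- 34 + 3.0 * cos(2 * pi * (doy - 130) / 365) + stats::rnorm(ndays, 0, 1.2)
    tmax[wet] <- tmax[wet] - 2
    tmax <- pmax(tmax, tmin + 1)

    radn <- 21 + 3.0 * cos(2 * pi * (doy - 100) / 365) + stats::rnorm(ndays, 0, 1.5)
    radn[wet] <- radn[wet] * 0.8
    radn <- pmin(pmax(radn, 3), 32)

    daily_weather(
      data.frame(year = 1L, doy = doy, rain = rain, tmax = tmax, tmin = tmin,
                 radn = radn),
      site = site$name, latitude = site$latitude
    )
  })
}

#' Construct and validate a daily weather series
#'
#' @param df Data.frame with columns \code{year}, \code{doy}, \code{rain},
#'   \code{tmax}, \code{tmin}, \code{radn}.
#' @param site Site name attribute.
#' @param latitude Degrees north; used to derive the photoperiod column.
#' @param twilight_angle Twilight depression used for the photoperiod (h).
#' @return A validated \code{daily_weather} data.frame.
#' @export
daily_weather <- function(df, site = "unknown", latitude, twilight_angle = 2.2) {
  need <- c("year", "doy", "rain", "tmax", "tmin", "radn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("weather is missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- df[order(df$year, df$doy), need, drop = FALSE]
  gaps <- which(diff(df$doy) != 1 & diff(df$year) == 0)
  if (length(gaps)) {
    stop("weather series has a missing day at doy ", df$doy[gaps[1]] + 1L,
         " (year ", df$year[gaps[1]], ")", call. = FALSE)
  }
  bad <- which(!is.finite(df$rain) | df$rain < 0)
  if (length(bad)) stop("negative or non-finite rain at doy ", df$doy[bad[1]],
                        " (year ", df$year[bad[1]], ")", call. = FALSE)
  bad <- which(df$tmax < df$tmin)
  if (length(bad)) stop("tmax < tmin at doy ", df$doy[bad[1]],
                        " (year ", df$year[bad[1]], ")", call. = FALSE)
  bad <- which(!is.finite(df$radn) | df$radn < 0)
  if (length(bad)) stop("negative or non-finite radiation at doy ", df$doy[bad[1]],
                        call. = FALSE)
  df$photoperiod <- daylength(latitude, df$doy, twilight_angle)
  attr(df, "site") <- site
  attr(df, "latitude") <- latitude
  class(df) <- c("daily_weather", "data.frame")
  df
}

#' Write a weather series to disk
#'
#' Two dialects are supported: a whitespace-separated \code{.met}-style file
#' with columns \code{year day radn maxt mint rain} (latitude recorded in a
#' \code{!} comment header) and a CSV with columns
#' \code{year,doy,rain,maxt,mint,radn}.
#'
#' @param series A \code{daily_weather} object.
#' @param path Output path; dialect chosen by extension unless \code{format}
#'   is given.
#' @param format \code{"met"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_weather <- function(series, path, format = c("auto", "met", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "met"
  }
  lat <- attr(series, "latitude")
  if (format == "met") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("! site = ", attr(series, "site")),
      paste0("! latitude = ", format(lat, digits = 10)),
      "year day radn maxt mint rain"
    ), con)
    utils::write.table(
      data.frame(year = series$year, day = series$doy,
                 radn = round(series$radn, 3), maxt = round(series$tmax, 3),
                 mint = round(series$tmin, 3), rain = round(series$rain, 3)),
      con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(year = series$year, doy = series$doy,
                     rain = round(series$rain, 3), maxt = round(series$tmax, 3),
                     mint = round(series$tmin, 3), radn = round(series$radn, 3),
                     latitude = lat)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a weather series from disk
#'
#' Accepts the \code{.met}-style and CSV dialects written by
#' \code{\link{write_weather}} (header names \code{day}/\code{doy} and
#' \code{maxt}/\code{tmax} etc. are both understood). The series is validated:
#' missing days, \code{tmax < tmin} or negative rain raise an error naming the
#' offending day.
#'
#' @param path File to read.
#' @param latitude Site latitude; if \code{NULL}, taken from the file
#'   (\code{! latitude =} comment or \code{latitude} column).
#' @param site Site name; default taken from the file when present.
#' @return A \code{daily_weather} data.frame.
#' @export
read_weather <- function(path, latitude = NULL, site = NULL) {
  first <- readLines(path, n = 20)
  is_csv <- grepl(",", first[1])
  if (is_csv) {
    df <- utils::read.csv(path)
    if (is.null(latitude) && "latitude" %in% names(df)) latitude <- df$latitude[1]
  } else {
    comments <- grep("^!", first, value = TRUE)
    if (is.null(latitude)) {
      m <- grep("latitude", comments, value = TRUE)
      if (length(m)) latitude <- as.numeric(sub(".*=\\s*", "", m[1]))
    }
    if (is.null(site)) {
      m <- grep("site", comments, value = TRUE)
      if (length(m)) site <- trimws(sub(".*=\\s*", "", m[1]))
    }
    df <- utils::read.table(path, header = TRUE, comment.char = "!")
  }
  if (is.null(latitude)) stop("latitude not found in file and not supplied",
                              call. = FALSE)
  if (is.null(site)) site <- "unknown"
  nm <- tolower(names(df))
  nm[nm == "day"] <- "doy"
  nm[nm == "maxt"] <- "tmax"
  nm[nm == "mint"] <- "tmin"
  names(df) <- nm
  daily_weather(df, site = site, latitude = latitude)
}

#' Fraction of annual rain inside the wet window
#'
#' @param series A \code{daily_weather} object.
#' @param window_start,window_end Day-of-year bounds of the nominal wet window.
#' @return Fraction in [0, 1] (1 when the season is completely dry).
#' @export
wet_window_fraction <- function(series, window_start, window_end) {
  tot <- sum(series$rain)
  if (tot <= 0) return(1)
  sum(series$rain[series$doy >= window_start & series$doy <= window_end]) / tot
}
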