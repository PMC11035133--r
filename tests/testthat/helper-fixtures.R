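# Shared fixtures: hand-built weather series and trajectory archetypes.

# A constant-forcing calendar year; photoperiod defaults to the latitude's
# astronomical value but can be overridden with a fixed value.
constant_weather <- function(tmax = 32, tmin = 22, radn = 22, rain = 0,
                             latitude = 12.5, ndays = 365,
                             photoperiod = NULL) {
  w <- daily_weather(
    data.frame(year = 1L, doy = seq_len(ndays),
               rain = rep_len(rain, ndays), tmax = tmax, tmin = tmin,
               radn = radn),
    site = "constant", latitude = latitude)
  if (!is.null(photoperiod)) w$photoperiod <- photoperiod
  w
}

# Wet-season weather: generous rains June-October so water never limits.
wet_weather <- function(latitude = 12.5) {
  rain <- numeric(365)
  rain[seq(155, 290, by = 2)] <- 14
  constant_weather(tmax = 33, tmin = 22, radn = 21, rain = rain,
                   latitude = latitude)
}

# Stress-scenario archetype trajectories (flat; decline from flowering;
# decline starting 200 degCd before flowering).
archetype_no_stress <- rep(1, 8)
archetype_flowering <- c(1, 1, 1, 1, 0.8, 0.6, 0.5, 0.4)
archetype_early     <- c(1, 0.85, 0.7, 0.6, 0.5, 0.4, 0.35, 0.3)

archetype_mixture <- function(n_per = 30, sd = 0.03, seed = 421) {
  set.seed(seed)
  mk <- function(a) t(vapply(seq_len(n_per), function(i)
    pmin(pmax(a + stats::rnorm(8, 0, sd), 1e-3), 1), numeric(8)))
  x <- rbind(mk(archetype_no_stress), mk(archetype_flowering),
             mk(archetype_early))
  list(x = x, labels = rep(c("no_stress", "flowering_stress",
                             "early_preflowering_stress"), each = n_per))
}

# Paired ensemble over the full 18-site network (season counts scaled down
# proportionally to the historical record lengths), shared by the heavier
# property tests; built once per session.
.ensemble_cache <- new.env(parent = emptyenv())
test_ensemble <- function() {
  if (!is.null(.ensemble_cache$ens)) return(.ensemble_cache$ens)
  specs <- mali_site_specs(seasons_scale = 0.12)
  man <- build_manifest(names(specs),
                        vapply(specs, function(s) s$n_seasons, integer(1)),
                        c("low_swhc", "high_swhc"),
                        c("CSM63E", "CSM335"), base_seed = 11)
  ens <- run_ensemble(man, specs)
  res <- summarize_ensemble(ens, seed = 11)
  .ensemble_cache$ens <- list(ens = ens, res = res, specs = specs)
  .ensemble_cache$ens
}
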