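# Goodness-of-fit statistics, divergence-line coverage, and the run manifest.

#' Goodness-of-fit statistics for observed vs predicted values
#'
#' Standard model-evaluation metrics: coefficient of determination (reported
#' both as the squared Pearson correlation, matching regression-line usage,
#' and as 1 - SSE/SST), MSE, RMSE, NRMSE (RMSE as a percentage of the
#' observed mean), MAE and MAPE, plus the coefficient of variation of the
#' observations.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return An object of class \code{fit_report}.
#' @examples
#' fit_statistics(c(2, 4), c(3, 5))  # MAE 1, RMSE 1, MAPE 37.5
#' @export
fit_statistics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  err <- observed - predicted
  mse <- mean(err^2)
  rmse <- sqrt(mse)
  mobs <- mean(observed)
  if (mobs == 0) stop("NRMSE undefined: observed mean is zero", call. = FALSE)
  if (any(observed == 0)) stop("MAPE undefined: zero observed values", call. = FALSE)
  sst <- sum((observed - mobs)^2)
  r2_pearson <- if (stats::sd(predicted) > 0 && stats::sd(observed) > 0) {
    stats::cor(observed, predicted)^2
  } else NA_real_
  structure(
    list(n = n,
         r_squared = r2_pearson,
         r_squared_1to1 = if (sst > 0) 1 - sum(err^2) / sst else NA_real_,
         mse = mse, rmse = rmse,
         nrmse = rmse / mobs * 100,
         mae = mean(abs(err)),
         mape = mean(abs(err) / abs(observed)) * 100,
         cv_observed = stats::sd(observed) / mobs * 100),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "Fit over n=%d: R2(pearson)=%.3f R2(1:1)=%.3f RMSE=%.3f NRMSE=%.1f%% MAE=%.3f MAPE=%.1f%%\n",
    x$n, x$r_squared, x$r_squared_1to1, x$rmse, x$nrmse, x$mae, x$mape))
  invisible(x)
}

#' Divergence-line coverage
#'
#' The divergence lines bracket the 1:1 line at plus/minus the observed
#' coefficient of variation times the observed value; a well-set-up model
#' should place about 80% of predictions inside this space.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @param threshold Coverage fraction required to pass.
#' @return List with \code{coverage} (fraction inside the lines), \code{cv}
#'   (of the observations, as a fraction), \code{pass}, and the per-point
#'   indicator \code{within}.
#' @export
divergence_coverage <- function(observed, predicted, threshold = 0.8) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) {
    stop("coefficient of variation undefined for a single point", call. = FALSE)
  }
  cv <- stats::sd(observed) / mean(observed)
  within <- abs(predicted - observed) <= abs(cv * observed)
  coverage <- mean(within)
  list(coverage = coverage, cv = cv, pass = coverage >= threshold,
       within = within)
}

#' Enumerate the run manifest
#'
#' Every site-season x soil x cultivar combination, with a reproducible
#' weather seed per site-season (shared across soils and cultivars so the
#' ensemble is paired on weather).
#'
#' @param sites Character vector of site names (or list of
#'   \code{\link{site_spec}}s, whose names are used).
#' @param seasons_per_site Integer vector (recycled) of seasons per site.
#' @param soils Character vector of soil names.
#' @param cultivars Character vector of cultivar names.
#' @param base_seed Seed from which per-season weather seeds derive.
#' @return A \code{run_manifest} data.frame with one row per run; its number
#'   of rows is sum(seasons) x length(soils) x length(cultivars).
#' @examples
#' nrow(build_manifest("A", 459, c("low", "high"), c("CSM63E", "CSM335")))
#' @export
build_manifest <- function(sites, seasons_per_site, soils, cultivars,
                           base_seed = 1) {
  if (is.list(sites)) sites <- vapply(sites, function(s) s$name, character(1))
  if (length(sites) < 1 || length(soils) < 1 || length(cultivars) < 1 ||
      any(seasons_per_site < 1)) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  seasons_per_site <- rep_len(seasons_per_site, length(sites))
  site_year <- do.call(rbind, lapply(seq_along(sites), function(i) {
    data.frame(site = sites[i], season = seq_len(seasons_per_site[i]),
               stringsAsFactors = FALSE)
  }))
  grid <- expand.grid(idx = seq_len(nrow(site_year)), soil = soils,
                      cultivar = cultivars, stringsAsFactors = FALSE)
  out <- data.frame(
    site = site_year$site[grid$idx], season = site_year$season[grid$idx],
    soil = grid$soil, cultivar = grid$cultivar, stringsAsFactors = FALSE)
  out$weather_seed <- (abs(base_seed) * 10007 + out$season * 131 +
                         match(out$site, unique(out$site)) * 17) %%
    .Machine$integer.max
  out$run_id <- seq_len(nrow(out))
  class(out) <- c("run_manifest", "data.frame")
  out
}

#' Simulate an ensemble of runs
#'
#' Runs the simulator over every row of a manifest, extracts the flowering-
#' anchored supply/demand trajectory of each completed run, and collects
#' season summaries. Weather is regenerated from each run's seed, so runs
#' sharing a site-season (different soils/cultivars) see identical weather.
#'
#' @param manifest A \code{\link{build_manifest}} data.frame.
#' @param site_specs Named list of \code{\link{site_spec}}s keyed by site
#'   name.
#' @param management A \code{\link{management_spec}}.
#' @param control A \code{\link{sim_control}}.
#' @return List with \code{summaries} (data.frame, one row per run),
#'   \code{trajectories} (matrix, rows = completed runs), \code{excluded}
#'   (data.frame of run_id and reason), \code{manifest}.
#' @export
run_ensemble <- function(manifest, site_specs,
                         management = management_spec(),
                         control = sim_control()) {
  stopifnot(inherits(manifest, "run_manifest"))
  soils <- list()
  cultivars <- list()
  weather_cache <- new.env(parent = emptyenv())
  summaries <- vector("list", nrow(manifest))
  traj <- vector("list", nrow(manifest))
  excl <- list()

  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    spec <- site_specs[[row$site]]
    if (is.null(spec)) stop("no site_spec for site '", row$site, "'", call. = FALSE)
    wkey <- paste(row$site, row$season, sep = "\r")
    w <- weather_cache[[wkey]]
    if (is.null(w)) {
      w <- generate_season(spec, row$weather_seed)
      weather_cache[[wkey]] <- w
    }
    if (is.null(soils[[row$soil]])) soils[[row$soil]] <- soil_preset(row$soil)
    if (is.null(cultivars[[row$cultivar]])) {
      cultivars[[row$cultivar]] <- cultivar(row$cultivar)
    }
    run <- grow_season(w, cultivars[[row$cultivar]], soils[[row$soil]],
                       management, control)
    s <- run$summary
    summaries[[r]] <- data.frame(
      run_id = row$run_id, site = row$site, season = row$season,
      isohyet = spec$isohyet_zone, soil = row$soil, cultivar = row$cultivar,
      sowing_doy = s$sowing_doy, flowering_doy = s$flowering_doy,
      maturity_doy = s$maturity_doy, max_leaf_no = s$max_leaf_no,
      peak_lai = s$peak_lai, biomass_kg_ha = s$biomass_kg_ha,
      grain_kg_ha = s$grain_kg_ha, matured = s$matured,
      stringsAsFactors = FALSE)
    tr <- tryCatch(extract_trajectory(run),
                   error = function(e) conditionMessage(e))
    if (is.character(tr)) {
      excl[[length(excl) + 1]] <- data.frame(run_id = row$run_id, reason = tr,
                                             stringsAsFactors = FALSE)
      traj[[r]] <- NULL
    } else {
      traj[[r]] <- tr
    }
  }
  ok <- !vapply(traj, is.null, logical(1))
  traj_mat <- do.call(rbind, traj[ok])
  if (!is.null(traj_mat)) rownames(traj_mat) <- manifest$run_id[ok]
  list(summaries = do.call(rbind, summaries),
       trajectories = traj_mat,
       trajectory_run_ids = manifest$run_id[ok],
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(run_id = integer(), reason = character()),
       manifest = manifest)
}

#' Scenario frequencies and yield distributions for an ensemble
#'
#' Clusters the ensemble's trajectories (all cultivars and soils jointly)
#' into k = 3 stress scenarios, labels them, weights each season by its
#' isohyet's data availability, and produces the weighted scenario-frequency
#' table and yield CPFs.
#'
#' @param ensemble Output of \code{\link{run_ensemble}}.
#' @param method,seed,n_restarts Passed to \code{\link{cluster_scenarios}}.
#' @return List with \code{scenarios} (\code{stress_scenarios}),
#'   \code{assignments} (per completed run: scenario, weight, identifiers),
#'   \code{frequencies} (weighted % per isohyet x soil x cultivar),
#'   \code{frequencies_overall} (per cultivar), \code{cpf} (per isohyet x
#'   cultivar weighted yield CDF), \code{yield_by_scenario} (weighted mean
#'   grain/biomass per cultivar x scenario).
#' @export
summarize_ensemble <- function(ensemble, method = "kmeans", seed = 1,
                               n_restarts = 25) {
  summ <- ensemble$summaries
  ids <- ensemble$trajectory_run_ids
  scen <- cluster_scenarios(ensemble$trajectories, k = 3, method = method,
                            seed = seed, n_restarts = n_restarts)
  asg <- summ[match(ids, summ$run_id), ]
  asg$scenario <- scen$labels[scen$cluster]

  counts <- tapply(asg$run_id, asg$isohyet, length)
  w <- season_weights(counts)
  asg$weight <- unname(w[asg$isohyet])

  freqs <- frequency_table(asg, group_by = c("isohyet", "soil", "cultivar"))
  freqs_overall <- frequency_table(asg, group_by = "cultivar")

  cpf <- do.call(rbind, lapply(split(asg, list(asg$isohyet, asg$cultivar),
                                     drop = TRUE), function(sub) {
    cbind(isohyet = sub$isohyet[1], cultivar = sub$cultivar[1],
          yield_cpf(sub$grain_kg_ha, sub$weight))
  }))
  rownames(cpf) <- NULL

  # scenario yield effects are plain means over member runs: the season
  # weights exist to compare scenario occurrence across the region, not to
  # re-weight within-scenario yield distributions
  ybs <- do.call(rbind, lapply(split(asg, list(asg$cultivar, asg$scenario),
                                     drop = TRUE), function(sub) {
    data.frame(cultivar = sub$cultivar[1], scenario = sub$scenario[1],
               n = nrow(sub),
               grain_kg_ha = mean(sub$grain_kg_ha),
               biomass_kg_ha = mean(sub$biomass_kg_ha),
               stringsAsFactors = FALSE)
  }))
  rownames(ybs) <- NULL

  list(scenarios = scen, assignments = asg, frequencies = freqs,
       frequencies_overall = freqs_overall, cpf = cpf,
       yield_by_scenario = ybs)
}

#' Run the full characterization pipeline
#'
#' Synthetic weather -> crop simulation -> trajectory extraction ->
#' clustering -> weighted summaries, written as CSVs. The configuration is a
#' list (or YAML file path) with elements \code{sites} (list of site entries:
#' name, latitude, isohyet, optional target_rainfall, n_seasons),
#' \code{soils}, \code{cultivars}, \code{seed}, \code{output_dir}, and
#' optional \code{cluster_method}.
#'
#' @param config List or path to a YAML config file.
#' @return Invisibly, the list of result objects; side effect: CSV artifacts
#'   (\code{manifest.csv}, \code{season_summary.csv},
#'   \code{trajectories.csv}, \code{centroids.csv},
#'   \code{scenario_frequency.csv}, \code{yield_cpf.csv},
#'   \code{exclusions.csv}) in \code{output_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (need in c("sites", "soils", "cultivars", "output_dir")) {
    if (is.null(config[[need]])) stop("config lacks '", need, "'", call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1
  bad <- setdiff(config$cultivars, c("CSM63E", "CSM335"))
  if (length(bad)) stop("unknown cultivar: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(config$soils, c("low_swhc", "high_swhc"))
  if (length(bad)) stop("unknown soil: ", paste(bad, collapse = ", "),
                        call. = FALSE)

  site_specs <- list()
  nseasons <- integer()
  for (s in config$sites) {
    spec <- site_spec(s$name, s$latitude, s$isohyet,
                      target_annual_rainfall = s$target_rainfall,
                      n_seasons = if (is.null(s$n_seasons)) 1L else s$n_seasons)
    site_specs[[s$name]] <- spec
    nseasons[s$name] <- spec$n_seasons
  }

  manifest <- build_manifest(names(site_specs), nseasons, config$soils,
                             config$cultivars, base_seed = config$seed)
  ens <- run_ensemble(manifest, site_specs)
  res <- summarize_ensemble(
    ens, method = if (is.null(config$cluster_method)) "kmeans" else
      config$cluster_method, seed = config$seed)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  utils::write.csv(as.data.frame(manifest), out("manifest.csv"), row.names = FALSE)
  utils::write.csv(ens$summaries, out("season_summary.csv"), row.names = FALSE)
  utils::write.csv(cbind(run_id = ens$trajectory_run_ids,
                         as.data.frame(ens$trajectories)),
                   out("trajectories.csv"), row.names = FALSE)
  utils::write.csv(cbind(label = res$scenarios$labels,
                         as.data.frame(res$scenarios$centroids)),
                   out("centroids.csv"), row.names = FALSE)
  utils::write.csv(res$frequencies, out("scenario_frequency.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cpf, out("yield_cpf.csv"), row.names = FALSE)
  utils::write.csv(ens$excluded, out("exclusions.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, ensemble = ens, results = res,
                 config = config))
}
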