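# Envirotyping: turn daily supply/demand series into interval trajectories
# anchored at flowering, cluster them into drought-stress scenarios, weight
# seasons by isohyet data availability, and summarize scenario frequencies and
# yield distributions.

SCENARIO_LABELS <- c("no_stress", "flowering_stress", "early_preflowering_stress")

trajectory_interval_names <- function() {
  c("m400_m300", "m300_m200", "m200_m100", "m100_0",
    "p0_100", "p100_200", "p200_300", "p300_400")
}

#' Extract the 8-interval supply/demand trajectory of one run
#'
#' Averages the daily S/D index over the eight 100-degree-day intervals
#' anchored at flowering: [-400,-300), [-300,-200), [-200,-100), [-100,0] on
#' the thermal-time axis before flowering and (0,100], (100,200], (200,300],
#' (300,400] after (the flowering day itself falls in the first
#' post-flowering interval). Runs that do not accumulate 400 degree-days on
#' both sides of flowering are rejected.
#'
#' @param daily_sd Daily S/D values.
#' @param daily_tt Daily degree-days (same length).
#' @param flowering_index Index of the flowering day in the series, or (for
#'   the \code{sorghum_season} method) taken from the run.
#' @param flowering_tt Optional exact cumulative degree-days at the flowering
#'   transition; defaults to the cumulative total at the start of the
#'   flowering day.
#' @return Named numeric vector of 8 interval means.
#' @export
extract_trajectory <- function(daily_sd, daily_tt, flowering_index,
                               flowering_tt = NULL) {
  if (inherits(daily_sd, "sorghum_season")) {
    run <- daily_sd
    if (!isTRUE(run$summary$matured) || is.na(run$summary$flowering_tt)) {
      stop("run did not reach flowering/maturity; trajectory unavailable",
           call. = FALSE)
    }
    return(extract_trajectory(run$daily$sd_ratio, run$daily$tt,
                              flowering_index = NA,
                              flowering_tt = run$summary$flowering_tt))
  }
  stopifnot(length(daily_sd) == length(daily_tt))
  cum <- cumsum(daily_tt)
  if (is.null(flowering_tt)) {
    if (flowering_index < 1 || flowering_index > length(daily_sd)) {
      stop("flowering_index out of range", call. = FALSE)
    }
    flowering_tt <- if (flowering_index > 1) cum[flowering_index - 1] else 0
  }
  dist <- cum - flowering_tt
  if (min(dist) > -400 || max(dist) < 400) {
    stop("insufficient thermal-time span: need 400 degree-days before and ",
         "after flowering (have ", round(-min(dist)), " / ",
         round(max(dist)), ")", call. = FALSE)
  }
  edges_pre <- c(-400, -300, -200, -100, 0)
  edges_post <- c(0, 100, 200, 300, 400)
  out <- numeric(8)
  for (b in 1:4) {  # pre: [lo, hi), last bin closed at 0
    lo <- edges_pre[b]; hi <- edges_pre[b + 1]
    sel <- if (b < 4) dist >= lo & dist < hi else dist >= lo & dist <= hi
    out[b] <- mean(daily_sd[sel])
  }
  for (b in 1:4) {  # post: (lo, hi]
    lo <- edges_post[b]; hi <- edges_post[b + 1]
    sel <- dist > lo & dist <= hi
    out[4 + b] <- mean(daily_sd[sel])
  }
  names(out) <- trajectory_interval_names()
  out
}

#' Cluster supply/demand trajectories into stress scenarios
#'
#' Partitions the 8-interval trajectories in raw S/D space (Euclidean
#' distance, no standardization) by k-means (best of \code{n_restarts}) or
#' PAM. Deterministic for a fixed seed.
#'
#' @param trajectories Numeric matrix, one row per run, 8 columns.
#' @param k Number of scenarios.
#' @param method \code{"kmeans"} or \code{"pam"}.
#' @param seed Integer seed for the k-means restarts.
#' @param n_restarts Number of k-means restarts.
#' @return An object of class \code{stress_scenarios}: \code{cluster}
#'   (assignment per run), \code{centroids} (k x 8), \code{objective},
#'   \code{method}, and \code{labels} (filled by
#'   \code{\link{label_scenarios}} when \code{k = 3}).
#' @export
cluster_scenarios <- function(trajectories, k = 3,
                              method = c("kmeans", "pam"), seed = 1,
                              n_restarts = 25) {
  method <- match.arg(method)
  x <- as.matrix(trajectories)
  if (ncol(x) != 8) stop("trajectories must have 8 interval columns", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop("k = ", k, " exceeds the number of distinct trajectories (",
         n_distinct, ")", call. = FALSE)
  }
  if (method == "kmeans") {
    fit <- with_seed(seed, stats::kmeans(x, centers = k, nstart = n_restarts,
                                         iter.max = 100))
    cl <- fit$cluster
    centroids <- fit$centers
    objective <- fit$tot.withinss
  } else {
    fit <- cluster::pam(x, k = k, metric = "euclidean")
    cl <- fit$clustering
    centroids <- fit$medoids
    objective <- fit$objective[["swap"]]
  }
  colnames(centroids) <- colnames(x) <- trajectory_interval_names()
  labels <- if (k == 3) label_scenarios(centroids) else NULL
  structure(
    list(cluster = cl, centroids = centroids, objective = objective,
         method = method, k = k, labels = labels, trajectories = x),
    class = "stress_scenarios"
  )
}

#' Label three scenario centroids
#'
#' The centroid whose mean S/D is at least \code{no_stress_threshold} across
#' all eight intervals is the no-stress scenario (two such centroids raise a
#' labeling-ambiguity error). Of the remaining two, the one whose first drop
#' of the index below 0.9 occurs earlier on the thermal-time axis (before the
#' flowering anchor for the archetypal case) is the early pre-flowering
#' stress; the other, whose onset coincides with flowering, is the flowering
#' stress. Ties on the drop position are broken by the lower overall mean.
#'
#' @param centroids 3 x 8 matrix of interval means.
#' @param no_stress_threshold Mean S/D defining the unstressed centroid.
#' @param drop_threshold S/D value whose first crossing defines stress onset.
#' @return Character vector of length 3: the scenario label of each centroid
#'   row, in order.
#' @export
label_scenarios <- function(centroids, no_stress_threshold = 0.95,
                            drop_threshold = 0.9) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != 3) stop("labeling requires exactly 3 centroids", call. = FALSE)
  m <- rowMeans(centroids)
  unstressed <- which(m >= no_stress_threshold)
  if (length(unstressed) > 1) {
    stop("labeling ambiguity: ", length(unstressed),
         " centroids are unstressed (mean >= ", no_stress_threshold,
         "); consider a smaller k", call. = FALSE)
  }
  if (length(unstressed) == 0) {
    stop("labeling ambiguity: no centroid has mean S/D >= ",
         no_stress_threshold, call. = FALSE)
  }
  labels <- character(3)
  labels[unstressed] <- "no_stress"
  rest <- setdiff(1:3, unstressed)
  onset <- vapply(rest, function(i) {
    w <- which(centroids[i, ] < drop_threshold)
    if (length(w)) min(w) else Inf
  }, numeric(1))
  ord <- order(onset, m[rest])
  labels[rest[ord[1]]] <- "early_preflowering_stress"
  labels[rest[ord[2]]] <- "flowering_stress"
  labels
}

#' Season weight equalizing isohyet contributions
#'
#' weight = max_seasons / (total_seasons * seasons_in_isohyet), so that each
#' isohyet zone's summed weight (weight x its season count) is the same
#' regardless of how many historical seasons it contributes.
#'
#' @param max_seasons Largest per-isohyet season count.
#' @param total_seasons Total seasons across all isohyets.
#' @param seasons_in_isohyet Season count of the isohyet in question.
#' @return The per-season weight (> 0).
#' @export
season_weight <- function(max_seasons, total_seasons, seasons_in_isohyet) {
  if (any(seasons_in_isohyet <= 0)) {
    stop("an isohyet with zero seasons cannot be weighted", call. = FALSE)
  }
  if (max_seasons > total_seasons) {
    stop("max_seasons cannot exceed total_seasons", call. = FALSE)
  }
  max_seasons / (total_seasons * seasons_in_isohyet)
}

#' Per-isohyet season weights from counts
#'
#' @param counts Named vector of season counts per isohyet.
#' @return Named vector of per-season weights.
#' @export
season_weights <- function(counts) {
  w <- season_weight(max(counts), sum(counts), counts)
  names(w) <- names(counts)
  w
}

#' Weighted scenario frequency table
#'
#' Weighted percentage of seasons in each stress scenario, by grouping
#' variables (typically isohyet x soil x cultivar). Rows sum to 100.
#'
#' @param assignments Data.frame with a \code{scenario} column, a
#'   \code{weight} column, and the grouping columns.
#' @param group_by Character vector of grouping column names.
#' @return Data.frame of groups x scenarios with percentage columns.
#' @export
frequency_table <- function(assignments,
                            group_by = c("isohyet", "soil", "cultivar")) {
  stopifnot(all(c("scenario", "weight") %in% names(assignments)))
  group_by <- intersect(group_by, names(assignments))
  scen <- intersect(SCENARIO_LABELS, unique(assignments$scenario))
  scen <- c(scen, setdiff(unique(assignments$scenario), scen))
  if (length(group_by) == 0) {
    tot <- sum(assignments$weight)
    pct <- vapply(scen, function(s)
      100 * sum(assignments$weight[assignments$scenario == s]) / tot, numeric(1))
    return(as.data.frame(as.list(pct)))
  }
  key <- interaction(assignments[group_by], drop = TRUE, sep = "\r")
  groups <- levels(key)
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- assignments[key == g, ]
    tot <- sum(sub$weight)
    pct <- vapply(scen, function(s)
      100 * sum(sub$weight[sub$scenario == s]) / tot, numeric(1))
    cbind(sub[1, group_by, drop = FALSE], as.data.frame(as.list(pct)))
  }))
  rownames(out) <- NULL
  out
}

#' Weighted cumulative probability curve of yields
#'
#' Weighted empirical CDF evaluated at the sorted yields: the production-risk
#' curve used to compare isohyets.
#'
#' @param yields Yields, kg ha-1.
#' @param weights Optional season weights (default equal).
#' @return Data.frame with \code{yield} (sorted) and \code{cum_prob}
#'   (non-decreasing, ending at 1).
#' @export
yield_cpf <- function(yields, weights = NULL) {
  if (length(yields) < 1) stop("need at least one yield", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(yields))
  stopifnot(length(weights) == length(yields), all(weights > 0))
  ord <- order(yields)
  data.frame(yield = yields[ord],
             cum_prob = cumsum(weights[ord]) / sum(weights))
}

#' Mean silhouette width of a scenario partition
#'
#' @param scenarios A \code{stress_scenarios} object.
#' @return Average silhouette width (single number), or \code{NA} for k = 1.
#' @export
silhouette_report <- function(scenarios) {
  stopifnot(inherits(scenarios, "stress_scenarios"))
  if (scenarios$k < 2) return(NA_real_)
  sil <- cluster::silhouette(scenarios$cluster,
                             stats::dist(scenarios$trajectories))
  mean(sil[, "sil_width"])
}

#' @export
print.stress_scenarios <- function(x, ...) {
  cat("Drought-stress scenarios: ", x$k, " clusters by ", x$method,
      " over ", nrow(x$trajectories), " trajectories\n", sep = "")
  tab <- table(x$cluster)
  for (i in seq_len(x$k)) {
    lab <- if (!is.null(x$labels)) x$labels[i] else paste0("cluster_", i)
    cat(sprintf("  %-28s n=%4d  centroid mean S/D %.3f\n", lab, tab[as.character(i)],
                mean(x$centroids[i, ])))
  }
  invisible(x)
}

#' @export
plot.stress_scenarios <- function(x, ...) {
  mid <- c(-350, -250, -150, -50, 50, 150, 250, 350)
  graphics::matplot(mid, t(x$centroids), type = "b", pch = 1:x$k, lty = 1,
                    xlab = "degree-days from flowering", ylab = "S/D ratio",
                    ylim = c(0, 1.05), ...)
  graphics::abline(v = 0, lty = 2)
  leg <- if (!is.null(x$labels)) x$labels else paste0("cluster_", seq_len(x$k))
  graphics::legend("bottomleft", legend = leg, pch = 1:x$k, col = 1:x$k, bty = "n")
  invisible(x)
}
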