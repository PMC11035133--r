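test_that("trajectory extraction averages the 8 flowering-anchored intervals", {
  # constant index: all intervals 1
  tt <- rep(25, 60)
  expect_equal(unname(extract_trajectory(rep(1, 60), tt, flowering_index = 30)),
               rep(1, 8))

  # step from 1 to 0.4 exactly at flowering: pre intervals 1, post 0.4
  sdv <- c(rep(1, 29), rep(0.4, 31))
  tr <- extract_trajectory(sdv, tt, flowering_index = 30)
  expect_equal(unname(tr), c(1, 1, 1, 1, 0.4, 0.4, 0.4, 0.4))

  # linear decline: brute-force day-by-day averaging oracle
  set.seed(7)
  tt <- stats::runif(80, 12, 22)
  sdv <- pmax(0.05, pmin(1, seq(1.1, 0.2, length.out = 80)))
  fi <- 45
  tr <- extract_trajectory(sdv, tt, flowering_index = fi)
  cum <- cumsum(tt)
  dist <- cum - cum[fi - 1]
  pre_edges <- list(c(-400, -300), c(-300, -200), c(-200, -100), c(-100, 0))
  oracle <- numeric(8)
  for (b in 1:4) {
    lo <- pre_edges[[b]][1]; hi <- pre_edges[[b]][2]
    sel <- if (b < 4) dist >= lo & dist < hi else dist >= lo & dist <= hi
    oracle[b] <- mean(sdv[sel])
    sel2 <- dist > (b - 1) * 100 & dist <= b * 100
    oracle[4 + b] <- mean(sdv[sel2])
  }
  expect_equal(unname(tr), oracle)

  # insufficient thermal-time span on either side is rejected
  expect_error(extract_trajectory(rep(1, 20), rep(25, 20), flowering_index = 10),
               "span")
})

test_that("clustering recovers archetypal stress scenarios", {
  mix <- archetype_mixture(n_per = 30, sd = 0.03)

  # k = 1: one cluster at the grand mean
  one <- cluster_scenarios(mix$x, k = 1)
  expect_true(all(one$cluster == 1))
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(mix$x)),
               tolerance = 1e-9)

  for (m in c("kmeans", "pam")) {
    fit <- cluster_scenarios(mix$x, k = 3, method = m, seed = 3)
    ari <- mclust::adjustedRandIndex(fit$labels[fit$cluster], mix$labels)
    expect_equal(ari, 1.0)
    # labels recover the construction of the archetypes
    expect_setequal(fit$labels, c("no_stress", "flowering_stress",
                                  "early_preflowering_stress"))
  }

  # both methods induce the identical partition on well-separated data
  km <- cluster_scenarios(mix$x, k = 3, method = "kmeans", seed = 3)
  pm <- cluster_scenarios(mix$x, k = 3, method = "pam")
  expect_equal(mclust::adjustedRandIndex(km$cluster, pm$cluster), 1.0)

  # determinism under a fixed seed
  expect_identical(cluster_scenarios(mix$x, seed = 5)$cluster,
                   cluster_scenarios(mix$x, seed = 5)$cluster)

  # degenerate: more clusters than distinct points
  same <- matrix(rep(1, 16), nrow = 2)
  expect_error(cluster_scenarios(same, k = 3), "distinct")

  # silhouette of a clean 3-way split is high
  expect_gt(silhouette_report(km), 0.6)
})

test_that("centroid labeling follows onset position and rejects ambiguity", {
  cent <- rbind(archetype_no_stress, archetype_flowering, archetype_early)
  expect_equal(label_scenarios(cent),
               c("no_stress", "flowering_stress", "early_preflowering_stress"))
  # permuted input order permutes labels consistently
  expect_equal(label_scenarios(cent[c(3, 1, 2), ]),
               c("early_preflowering_stress", "no_stress", "flowering_stress"))
  # two unstressed centroids: ambiguity
  expect_error(label_scenarios(rbind(rep(1, 8), rep(0.99, 8), rep(0.5, 8))),
               "ambiguity")
  expect_error(label_scenarios(matrix(1, 3, 8)), "ambiguity")
})

test_that("season weights equalize isohyet totals", {
  # symmetric case: Z zones with n seasons each
  w <- season_weight(10, 40, 10)
  expect_equal(w, 1 / 40)

  # counts {10, 20}: per-isohyet weighted totals are both max/total = 2/3
  ws <- season_weights(c(a = 10, b = 20))
  expect_equal(unname(ws), c(20 / 300, 20 / 600))
  expect_equal(unname(ws * c(10, 20)), c(2 / 3, 2 / 3))

  # scale invariance of weight shares
  ws2 <- season_weights(c(a = 30, b = 60))
  expect_equal(unname(ws["a"] / ws["b"]), unname(ws2["a"] / ws2["b"]))

  expect_error(season_weight(10, 30, 0), "zero seasons")
})

test_that("frequency tables are weighted percentages summing to 100", {
  asg <- data.frame(
    isohyet = c("A", "A", "B", "B"),
    soil = "low", cultivar = "X",
    scenario = c("no_stress", "flowering_stress", "no_stress", "no_stress"),
    weight = c(2, 1, 1, 1))
  tab <- frequency_table(asg, group_by = "isohyet")
  # brute-force weighted count oracle
  expect_equal(tab$no_stress[tab$isohyet == "A"], 100 * 2 / 3)
  expect_equal(tab$flowering_stress[tab$isohyet == "A"], 100 / 3)
  expect_equal(tab$no_stress[tab$isohyet == "B"], 100)
  scen_cols <- setdiff(names(tab), "isohyet")
  expect_equal(rowSums(tab[scen_cols]), rep(100, nrow(tab)), tolerance = 1e-9)

  # equal weights reduce to raw proportions
  asg$weight <- 1
  tab <- frequency_table(asg, group_by = "isohyet")
  expect_equal(tab$no_stress[tab$isohyet == "A"], 50)

  # single scenario: 100
  tab1 <- frequency_table(data.frame(scenario = "no_stress", weight = 5,
                                     isohyet = "A"), group_by = "isohyet")
  expect_equal(tab1$no_stress, 100)
})

test_that("yield CPFs are weighted empirical CDFs", {
  cpf <- yield_cpf(c(3, 1, 4, 2))
  expect_equal(cpf$yield, 1:4)
  expect_equal(cpf$cum_prob, c(0.25, 0.5, 0.75, 1))

  # identical yields: a single jump to 1
  cpf1 <- yield_cpf(rep(1500, 5))
  expect_equal(cpf1$cum_prob[5], 1)

  # weighted toy vs a resampling oracle: replicate each yield by its integer
  # weight and compare the unweighted CDF at matching yields
  y <- c(10, 20, 30); wt <- c(1, 2, 3)
  cpf_w <- yield_cpf(y, wt)
  cpf_r <- yield_cpf(rep(y, wt))
  expect_equal(cpf_w$cum_prob, cpf_r$cum_prob[cumsum(wt)])
  expect_true(all(diff(cpf_w$cum_prob) >= 0))
})
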