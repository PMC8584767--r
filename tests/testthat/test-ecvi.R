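# Alkire-Foster ECVI: schema, cutoffs, index arithmetic, decompositions
# and standard errors, checked against hand computation and a
# first-principles enumeration oracle.

test_that("the default schema carries the equal-within-dimension weights", {
  sch <- ecvi_schema()
  expect_equal(nrow(sch), 18L)
  expect_equal(sum(sch$weight), 1, tolerance = 1e-12)
  by_dim <- tapply(sch$weight, sch$dimension, sum)
  expect_equal(as.numeric(by_dim), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(unique(sch$weight[sch$dimension == "exposure"]), 1 / 21)
  expect_equal(unique(sch$weight[sch$dimension == "susceptibility"]), 1 / 15)
  expect_equal(unique(sch$weight[sch$dimension == "adaptive_capacity"]),
               1 / 18)
  # income threshold presets
  expect_equal(sch$threshold[sch$indicator_id == "income_per_capita"], 296.8)
  expect_equal(ecvi_schema(255)$threshold[10], 255)
})

make_panel <- function(n, seed = 1) {
  set.seed(seed)
  sch <- ecvi_schema()
  panel <- tibble::tibble(region_id = sprintf("P%02d", seq_len(n)),
                          population = exp(rnorm(n, 12, 0.4)))
  for (id in sch$indicator_id) {
    panel[[id]] <- if (id == "income_per_capita") runif(n, 150, 900)
                   else runif(n)
  }
  panel
}

test_that("deprivation cutoffs use inclusive quartile bounds", {
  sch <- ecvi_schema()
  panel <- make_panel(8)
  panel$txx <- 1:8 # upper-quartile rule, explicit sort oracle
  dep <- apply_deprivation_cutoffs(panel, sch)
  q3 <- oracle_percentile(1:8, 0.75)
  expect_equal(dep$deprived[dep$indicator_id == "txx"],
               as.integer(1:8 >= q3))

  # lower-quartile rule is inclusive too
  panel$prop_literate <- 8:1
  dep <- apply_deprivation_cutoffs(panel, sch)
  q1 <- oracle_percentile(1:8, 0.25)
  expect_equal(dep$deprived[dep$indicator_id == "prop_literate"],
               as.integer(8:1 <= q1))

  # income rule is strictly below: a region exactly at the cutoff is not
  # deprived
  panel$income_per_capita <- c(296.8, 296.79, 500, 100, 400, 296.81, 50, 300)
  dep <- apply_deprivation_cutoffs(panel, sch)
  expect_equal(dep$deprived[dep$indicator_id == "income_per_capita"],
               as.integer(c(0, 1, 0, 1, 0, 0, 1, 0)))

  # degenerate constant indicator flags everyone, with a warning
  panel$dtr <- rep(5, 8)
  expect_warning(depc <- apply_deprivation_cutoffs(panel, sch), "constant")
  expect_true(all(depc$deprived[depc$indicator_id == "dtr"] == 1))

  # missing values are hard errors naming region and indicator
  panel$cdd[3] <- NA
  expect_error(suppressWarnings(apply_deprivation_cutoffs(panel, sch)),
               "cdd.*P03")
})

test_that("weighted scores reproduce the dimensional weight identities", {
  sch <- ecvi_schema()
  panel <- make_panel(6)
  dep <- apply_deprivation_cutoffs(panel, sch)
  # overwrite flags to controlled patterns
  dep$deprived <- 0L
  dep$deprived[dep$region_id == "P01" &
                 dep$indicator_id %in% sch$indicator_id[sch$dimension ==
                                                          "exposure"]] <- 1L
  dep$deprived[dep$region_id == "P02"] <- 1L
  sc <- weighted_score(dep, sch)
  expect_equal(sc$score[sc$region_id == "P01"], 1 / 3, tolerance = 1e-12)
  expect_equal(sc$score[sc$region_id == "P02"], 1, tolerance = 1e-12)
  expect_equal(sc$score[sc$region_id == "P03"], 0)

  # weight sums off by more than 1e-9 are rejected
  bad <- sch; bad$weight[1] <- bad$weight[1] + 1e-6
  expect_error(weighted_score(dep, bad), "sum to 1")
})

test_that("compute_ecvi matches hand computation and censoring limits", {
  # two equal-population regions, c = (1/3, 0.20), k_p = 0.25
  sc <- tibble::tibble(region_id = c("a", "b"), score = c(1 / 3, 0.20))
  pop <- c(a = 1000, b = 1000)
  res <- compute_ecvi(sc, pop, 0.25)
  expect_equal(res$ch, 0.5)
  expect_equal(res$di, 1 / 3)
  expect_equal(res$ecvi, 1 / 6)

  # empty censored set collapses everything to zero
  res0 <- compute_ecvi(sc, pop, 0.9)
  expect_equal(c(res0$ch, res0$di, res0$ecvi), c(0, 0, 0))

  # ECVI = CH x DI exactly on arbitrary panels
  p <- random_score_panel(40, seed = 4)
  r <- compute_ecvi(p, p[c("region_id", "population")], 0.25)
  expect_equal(r$ecvi, r$ch * r$di, tolerance = 1e-15)
  expect_gte(r$di, 0.25 * (r$ch > 0))

  # population-scale invariance
  p2 <- p; p2$population <- p2$population * 1e3
  r2 <- compute_ecvi(p2, p2[c("region_id", "population")], 0.25)
  expect_equal(r2[1:3], r[1:3], tolerance = 1e-12)
})

test_that("AF monotonicity: flipping a flag 0 -> 1 never lowers the ECVI", {
  sch <- ecvi_schema()
  panel <- make_panel(10, seed = 7)
  dep <- apply_deprivation_cutoffs(panel, sch)
  pops <- panel[c("region_id", "population")]
  base_val <- compute_ecvi(dep, pops, 0.25, schema = sch)$ecvi
  zeros <- which(dep$deprived == 0L)
  for (i in sample(zeros, 12)) {
    dep2 <- dep
    dep2$deprived[i] <- 1L
    expect_gte(compute_ecvi(dep2, pops, 0.25, schema = sch)$ecvi, base_val)
  }
})

test_that("ECVI and CH are nonincreasing in k_p; DI nondecreasing on CH>0", {
  p <- random_score_panel(30, seed = 11)
  grid <- seq(0.05, 1, 0.05)
  res <- t(vapply(grid, function(k) {
    r <- compute_ecvi(p, p[c("region_id", "population")], k)
    c(r$ch, r$di, r$ecvi)
  }, numeric(3)))
  expect_true(all(diff(res[, 1]) <= 1e-12))
  expect_true(all(diff(res[, 3]) <= 1e-12))
  pos <- res[, 1] > 0
  expect_true(all(diff(res[pos, 2]) >= -1e-12))
})

test_that("both decompositions agree with the enumeration oracle", {
  sch <- ecvi_schema()
  set.seed(13)
  for (rep in 1:5) {
    panel <- make_panel(12, seed = 20 + rep)
    dep <- apply_deprivation_cutoffs(panel, sch)
    pops <- panel[c("region_id", "population")]
    flags <- matrix(dep$deprived[order(match(dep$region_id, panel$region_id),
                                       match(dep$indicator_id,
                                             sch$indicator_id))],
                    nrow = 12, byrow = TRUE)
    ora <- oracle_af(flags, sch$weight, panel$population, 0.25)
    got <- compute_ecvi(dep, pops, 0.25, schema = sch)
    expect_equal(got$ch, ora$ch, tolerance = 1e-12)
    expect_equal(got$di, ora$di, tolerance = 1e-12)
    expect_equal(got$ecvi, ora$ecvi, tolerance = 1e-12)

    di <- decompose_by_indicator(dep, pops, 0.25, sch)
    expect_equal(di$indicator$ch_indicator, ora$ch_ind, tolerance = 1e-12)
    expect_equal(sum(sch$weight * ora$ch_ind), got$ecvi, tolerance = 1e-12)
    if (got$ecvi > 0) {
      expect_equal(sum(di$indicator$contribution), 1, tolerance = 1e-12)
      expect_equal(sum(di$dimension$contribution), 1, tolerance = 1e-12)
    }

    grp <- tibble::tibble(region_id = panel$region_id,
                          group = rep(c("g1", "g2"), c(7, 5)))
    ds <- decompose_by_subgroup(dep, pops, grp, 0.25, schema = sch)
    expect_equal(sum(ds$population_share * ds$ecvi), got$ecvi,
                 tolerance = 1e-12)
    if (got$ecvi > 0) {
      expect_equal(sum(ds$contribution), 1, tolerance = 1e-12)
    }
  }
})

test_that("subgroup decomposition handles the trivial partitions", {
  p <- random_score_panel(10, seed = 17)
  pops <- p[c("region_id", "population")]
  whole <- tibble::tibble(region_id = p$region_id, group = "all")
  ds <- decompose_by_subgroup(p, pops, whole, 0.25)
  expect_equal(ds$contribution, 1, tolerance = 1e-12)

  # vulnerable regions concentrated in one subgroup: it contributes 1
  p$score <- c(rep(0.6, 4), rep(0.05, 6))
  grp <- tibble::tibble(region_id = p$region_id,
                        group = rep(c("vul", "safe"), c(4, 6)))
  ds2 <- decompose_by_subgroup(p, pops, grp, 0.25)
  expect_equal(ds2$contribution[ds2$group == "vul"], 1, tolerance = 1e-12)
  expect_equal(ds2$contribution[ds2$group == "safe"], 0)

  # incomplete partitions are rejected
  expect_error(decompose_by_subgroup(p, pops, grp[-1, ], 0.25), "cover")
})

test_that("bootstrap SE matches a closed-form two-point oracle", {
  # two-point c-distribution, equal populations: the resampled ECVI is
  # s * B(n, p)/n with s the vulnerable score, so its SD has a closed form
  n <- 10; s <- 0.5
  p <- tibble::tibble(region_id = sprintf("T%02d", 1:n),
                      score = rep(c(s, 0.05), c(4, 6)),
                      population = rep(1, n))
  se <- estimate_se(p, p[c("region_id", "population")], 0.25,
                    method = "bootstrap", B = 5000, seed = 99)
  closed <- s * sqrt(0.4 * 0.6 / n)
  expect_lt(abs(se$ecvi_se - closed) / closed, 0.05)

  # no variation -> SE exactly zero under both methods
  flat <- tibble::tibble(region_id = c("x", "y", "z"), score = 0.5,
                         population = 2)
  for (m in c("bootstrap", "linearization")) {
    se0 <- estimate_se(flat, flat[c("region_id", "population")], 0.25,
                       method = m, B = 200)
    expect_equal(unlist(se0), c(ch_se = 0, di_se = 0, ecvi_se = 0))
  }

  # duplicating every region roughly halves the linearized variance
  pd <- dplyr::bind_rows(p, dplyr::mutate(p, region_id = paste0(region_id,
                                                                "b")))
  v1 <- estimate_se(p, p[c("region_id", "population")], 0.25,
                    method = "linearization")$ecvi_se^2
  v2 <- estimate_se(pd, pd[c("region_id", "population")], 0.25,
                    method = "linearization")$ecvi_se^2
  expect_lt(abs(v2 / v1 - 0.5), 0.06)

  expect_warning(estimate_se(p, p[c("region_id", "population")], 0.25,
                             B = 10), "B < 50")
})
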