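# Grade of Membership model: conjugate reductions, label alignment,
# simplex invariants and parameter recovery on data with known truth.

test_that("K = 1 fit reduces to the conjugate multinomial posterior", {
  set.seed(31)
  Y <- tibble::tibble(
    region_id = rep(sprintf("G%03d", 1:80), each = 2),
    item_id = rep(c("item1", "item2"), 80),
    category = sample.int(5, 160, replace = TRUE,
                          prob = c(.1, .2, .4, .2, .1))
  )
  fit <- fit_gom(Y, gom_config(K = 1, n_iterations = 2000, burn_in = 500,
                               seed = 4))
  for (j in 1:2) {
    counts <- tabulate(Y$category[Y$item_id == paste0("item", j)], 5)
    # exact conjugate posterior mean under the Dirichlet(1) prior
    post_mean <- (counts + 1) / (80 + 5)
    draws_sd <- apply(fit$lambda_draws[, 1, j, ], 2, sd)
    mcse <- draws_sd / sqrt(2000) # draws are iid for K = 1
    expect_true(all(abs(fit$lambda_mean[1, j, ] - post_mean) < 4 * mcse))
    # and close to the empirical frequencies up to the O(1/N) prior shift
    expect_true(all(abs(fit$lambda_mean[1, j, ] - counts / 80) < 0.05))
  }
})

test_that("every draw satisfies the simplex constraints", {
  g_true <- rdir_fixture(40, c(0.3, 0.3), seed = 8)
  Y <- sample_gom_data(g_true, separated_lambda(), seed = 9)
  fit <- fit_gom(Y, gom_config(n_iterations = 300, burn_in = 100, seed = 5))
  expect_true(all(abs(apply(fit$g_draws, c(1, 2), sum) - 1) < 1e-12))
  expect_true(all(fit$g_draws >= 0))
  expect_true(all(abs(apply(fit$lambda_draws, c(1, 2, 3), sum) - 1) < 1e-12))
  expect_true(all(fit$lambda_draws >= 0))
  expect_true(all(abs(rowSums(fit$xi_draws) - 1) < 1e-12))

  # the fitted cell probabilities reproduce each item's marginal category
  # frequencies on average (mixture mean identity)
  M <- fit$Y
  for (j in seq_along(fit$items)) {
    marg <- tabulate(M[, j], fit$L) / nrow(M)
    fitted <- colMeans(fit$g_means %*% fit$lambda_mean[, j, ])
    expect_true(all(abs(fitted - marg) < 0.1))
  }
})

test_that("degenerate items and missing cells are hard errors", {
  Y <- tibble::tibble(region_id = rep(sprintf("G%d", 1:6), each = 2),
                      item_id = rep(c("a", "b"), 6),
                      category = c(rbind(rep(1L, 6), c(1:5, 1L))))
  expect_error(fit_gom(Y, gom_config(n_iterations = 10, burn_in = 2)),
               "degenerate item")
  expect_error(fit_gom(Y[-1, ], gom_config(n_iterations = 10, burn_in = 2)),
               "exactly one category")
})

test_that("label alignment undoes a constructed swapped chain", {
  set.seed(21)
  K <- 2; J <- 3; L <- 4; n <- 40
  lam_a <- separated_lambda(J, L)
  base <- array(rep(lam_a, each = n), c(n, K, J, L)) +
    array(rnorm(n * K * J * L, 0, 0.01), c(n, K, J, L))
  g <- array(runif(n * 10 * K), c(n, 10, K))
  xi <- matrix(0.5, n, K)
  ll <- rnorm(n)
  ll[1] <- 100 # pin the reference draw to an unflipped one
  swapped <- list(lambda = base, g = g, xi = xi, loglik = ll)
  flip <- seq(2, n, by = 2)
  swapped$lambda[flip, , , ] <- swapped$lambda[flip, 2:1, , ]
  swapped$g[flip, , ] <- swapped$g[flip, , 2:1]
  aligned <- align_labels(swapped)
  expect_equal(aligned$lambda, base, tolerance = 1e-12)
  expect_equal(aligned$g, g, tolerance = 1e-12)

  # already-aligned draws and K = 1 are no-ops
  expect_equal(align_labels(list(lambda = base, g = g, xi = xi,
                                 loglik = ll)),
               list(lambda = base, g = g, xi = xi, loglik = ll))
  one <- list(lambda = base[, 1, , , drop = FALSE], g = g[, , 1,
              drop = FALSE], xi = xi[, 1, drop = FALSE], loglik = ll)
  expect_identical(align_labels(one), one)
})

test_that("profile classification applies the membership tier cutoffs", {
  g <- rbind(c(0.92, 0.08), c(0.80, 0.20), c(0.60, 0.40), c(0.10, 0.90))
  rownames(g) <- c("a", "b", "c", "d")
  asg <- classify_profiles(g)
  expect_equal(asg$profile, c(1L, 1L, 1L, 2L))
  expect_equal(asg$tier,
               c("extreme", "high-mixed", "medium-mixed", "extreme"))

  # exact tie goes to the lower profile index with a warning
  gt <- rbind(c(0.5, 0.5)); rownames(gt) <- "t"
  expect_warning(asgt <- classify_profiles(gt), "tie")
  expect_equal(asgt$profile, 1L)
  expect_equal(asgt$tier, "medium-mixed")

  # boundary values sit in the tier whose cutoff they meet
  gb <- rbind(c(0.90, 0.10), c(0.75, 0.25)); rownames(gb) <- c("x", "y")
  expect_equal(classify_profiles(gb)$tier, c("extreme", "high-mixed"))
})

test_that("memberships are recovered on the well-separated design", {
  acc <- replicate(2, NA_real_)
  for (r in 1:2) {
    g_true <- rdir_fixture(60, 0.5 * c(0.5, 0.5), seed = 100 + r)
    Y <- sample_gom_data(g_true, separated_lambda(), seed = 200 + r)
    fit <- fit_gom(Y, gom_config(n_iterations = 800, burn_in = 400,
                                 seed = 300 + r))
    # map fitted profiles onto the truth by the better of the two labelings
    est <- fit$g_means[paste0("G", sprintf("%03d", 1:60)), ]
    agree1 <- mean((est[, 1] >= 0.5) == (g_true[, 1] >= 0.5))
    est_use <- if (agree1 >= 0.5) est else est[, 2:1]
    clear <- apply(g_true, 1, max) >= 0.75
    hit <- (est_use[, 1] >= 0.5) == (g_true[, 1] >= 0.5)
    acc[r] <- mean(hit[clear])
    # mean absolute error of the dominant membership stays small
    expect_lt(mean(abs(est_use[clear, 1] - g_true[clear, 1])), 0.15)
  }
  expect_true(all(acc >= 0.9))
})

test_that("fit is deterministic in the seed and exchangeable in regions", {
  g_true <- rdir_fixture(30, c(0.25, 0.25), seed = 77)
  Y <- sample_gom_data(g_true, separated_lambda(), seed = 78)
  f1 <- fit_gom(Y, gom_config(n_iterations = 200, burn_in = 100, seed = 6))
  f2 <- fit_gom(Y, gom_config(n_iterations = 200, burn_in = 100, seed = 6))
  expect_identical(f1$lambda_draws, f2$lambda_draws)
  expect_identical(f1$g_draws, f2$g_draws)

  # permuting input row order leaves the fit unchanged (regions are keyed
  # by id, and the sampler is exchangeable in them)
  f3 <- fit_gom(Y[sample(nrow(Y)), ],
                gom_config(n_iterations = 200, burn_in = 100, seed = 6))
  expect_identical(f1$g_means, f3$g_means)
})

test_that("lower alpha0 yields more extreme recovered memberships", {
  sharp <- rdir_fixture(200, 0.1 * c(0.5, 0.5), seed = 12)
  flat <- rdir_fixture(200, 50 * c(0.5, 0.5), seed = 12)
  expect_gt(mean(apply(sharp, 1, max) > 0.9), 0.8)
  expect_lt(mean(apply(flat, 1, max) > 0.9), 0.2)
  # recovered spread follows generation: fit both and compare mean extremity
  Y_sharp <- sample_gom_data(rdir_fixture(50, 0.3 * c(0.5, 0.5), seed = 13),
                             separated_lambda(), seed = 14)
  Y_flat <- sample_gom_data(rdir_fixture(50, 5 * c(0.5, 0.5), seed = 15),
                            separated_lambda(), seed = 16)
  cfg <- gom_config(n_iterations = 400, burn_in = 200, seed = 17)
  f_sharp <- fit_gom(Y_sharp, cfg)
  # the flat design mixes slowly at this short chain length; the
  # convergence warning is expected here
  f_flat <- suppressWarnings(fit_gom(Y_flat, cfg))
  expect_gt(mean(apply(f_sharp$g_means, 1, max)),
            mean(apply(f_flat$g_means, 1, max)))
  expect_lt(f_sharp$alpha0, f_flat$alpha0)
})

test_that("profile characterization flags cells above the marginal ratio", {
  g_true <- rdir_fixture(60, 0.4 * c(0.5, 0.5), seed = 19)
  lam <- separated_lambda()
  Y <- sample_gom_data(g_true, lam, seed = 20)
  fit <- fit_gom(Y, gom_config(n_iterations = 500, burn_in = 250, seed = 21))
  chars <- characterize_profiles(fit)
  # threshold arithmetic: salient iff lambda >= 1.2 x marginal
  expect_equal(chars$salient,
               chars$marginal > 0 &
                 chars$lambda_mean >= 1.2 * chars$marginal)
  # each profile loads on opposite extreme categories of every item, so
  # category 1 is salient for one profile and category 5 for the other
  sal1 <- chars[chars$salient & chars$category == 1, ]
  sal5 <- chars[chars$salient & chars$category == 5, ]
  expect_true(all(table(sal1$profile) > 0) && length(unique(sal1$profile)) == 1)
  expect_true(all(table(sal5$profile) > 0) && length(unique(sal5$profile)) == 1)
  expect_false(unique(sal1$profile) == unique(sal5$profile))
})
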