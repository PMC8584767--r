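#' Bayesian Grade of Membership model for categorical climate profiles
#'
#' A mixed-membership model for regions x items categorical data: each region
#' i holds a membership vector g_i on the K-simplex and each extreme profile
#' k has, for every item j, a category-response distribution lambda_kj. on
#' the L-simplex, so P(Y_ijl = 1) = sum_k g_ik lambda_kjl. Memberships are
#' i.i.d. Dirichlet(alpha) with the Erosheva reparameterization
#' alpha = alpha0 * xi (xi on the simplex = expected profile proportions,
#' alpha0 = spread: lower alpha0 means memberships closer to the simplex
#' vertices, i.e. more clear-cut extreme profiles).
#'
#' Estimation is by a conjugate Gibbs sampler with per-(region, item) latent
#' profile indicators z_ij: z from its full conditional, g_i | z conjugate
#' Dirichlet, lambda | z conjugate Dirichlet, and a Metropolis step for
#' (xi, alpha0) given the memberships. Label switching is undone post hoc by
#' [align_labels()].
#'
#' @name gom_model
NULL

#' Configuration for the Grade of Membership sampler
#'
#' @param K number of extreme profiles (default 2).
#' @param n_iterations post-burn-in Gibbs draws kept (default 5000).
#' @param burn_in draws discarded before retention (default 2500).
#' @param seed RNG seed; identical config + seed gives identical draws.
#' @param prior_lambda symmetric Dirichlet concentration for each
#'   profile-item response distribution (default 1, uniform on the simplex).
#' @param prior_xi symmetric Dirichlet concentration for the expected
#'   profile proportions xi (default 1).
#' @param prior_alpha0_shape,prior_alpha0_rate Gamma prior on the membership
#'   spread alpha0 (default shape 1, rate 0.5 — diffuse, prior mean 2).
#' @param alpha0_init,mh_sd_alpha0,xi_proposal_conc initial value and
#'   Metropolis proposal scales for the (alpha0, xi) step.
#' @return a `gom_config` list.
#' @export
gom_config <- function(K = 2L, n_iterations = 5000L, burn_in = 2500L,
                       seed = 1L, prior_lambda = 1, prior_xi = 1,
                       prior_alpha0_shape = 1, prior_alpha0_rate = 0.5,
                       alpha0_init = 1, mh_sd_alpha0 = 0.4,
                       xi_proposal_conc = 50) {
  stopifnot(K >= 1L, n_iterations >= 1L, burn_in >= 0L,
            burn_in < burn_in + n_iterations,
            prior_lambda > 0, prior_xi > 0,
            prior_alpha0_shape > 0, prior_alpha0_rate > 0, alpha0_init > 0)
  structure(list(K = as.integer(K), n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 prior_lambda = prior_lambda, prior_xi = prior_xi,
                 prior_alpha0_shape = prior_alpha0_shape,
                 prior_alpha0_rate = prior_alpha0_rate,
                 alpha0_init = alpha0_init, mh_sd_alpha0 = mh_sd_alpha0,
                 xi_proposal_conc = xi_proposal_conc),
            class = "gom_config")
}

# long categorical matrix -> N x J integer matrix + labels
.as_response_matrix <- function(Y) {
  req <- c("region_id", "item_id", "category")
  if (!all(req %in% names(Y))) {
    stop("categorical matrix needs columns region_id, item_id, category")
  }
  regions <- sort(unique(Y$region_id))
  items <- sort(unique(Y$item_id))
  if (nrow(Y) != length(regions) * length(items) ||
      anyDuplicated(Y[c("region_id", "item_id")]) > 0L) {
    stop("categorical matrix must have exactly one category per ",
         "(region, item) cell")
  }
  if (anyNA(Y$category)) stop("missing cells are not allowed")
  M <- matrix(NA_integer_, length(regions), length(items),
              dimnames = list(regions, items))
  M[cbind(match(Y$region_id, regions), match(Y$item_id, items))] <-
    as.integer(Y$category)
  M
}

#' Fit the Grade of Membership model by Gibbs sampling
#'
#' @param Y long categorical matrix with columns `region_id`, `item_id`,
#'   `category` (integer codes `1..L`), one row per (region, item).
#' @param config a [gom_config()].
#' @return an object of class `gom_fit`: post-burn-in, label-aligned draws
#'   (`lambda_draws` `[draw, K, J, L]`, `g_draws` `[draw, N, K]`, `xi_draws`,
#'   `alpha0_draws`, `loglik`), posterior summaries (`g_means`,
#'   `lambda_mean`, `xi`, `alpha0`) and the region/item labels.
#' @export
fit_gom <- function(Y, config = gom_config()) {
  M <- .as_response_matrix(Y)
  N <- nrow(M); J <- ncol(M)
  L <- max(M)
  K <- config$K
  if (K > N) stop("K must not exceed the number of regions")
  n_cat <- apply(M, 2L, function(col) length(unique(col)))
  if (any(n_cat < 2L) && K > 1L) {
    stop("degenerate item(s) with a single observed category: ",
         paste(colnames(M)[n_cat < 2L], collapse = ", "))
  }

  n_keep <- config$n_iterations
  n_tot <- config$burn_in + n_keep
  # linear index into a J x L lambda slab for the observed responses
  obs_idx <- as.vector(rep(seq_len(J), each = N) + (M - 1L) * J)

  lambda_draws <- array(NA_real_, c(n_keep, K, J, L))
  g_draws <- array(NA_real_, c(n_keep, N, K))
  xi_draws <- matrix(NA_real_, n_keep, K)
  alpha0_draws <- numeric(n_keep)
  loglik <- numeric(n_keep)

  with_seed(config$seed, {
    # initial values
    g <- rdirichlet(N, rep(1, K))
    lambda <- array(stats::rgamma(K * J * L, 1), c(K, J, L))
    lambda <- lambda / rep(apply(lambda, c(1, 2), sum), times = L)
    alpha0 <- config$alpha0_init
    xi <- rep(1 / K, K)

    for (it in seq_len(n_tot)) {
      ## z | g, lambda  (full conditional, per (i, j) cell)
      W <- array(NA_real_, c(N, J, K))
      for (k in seq_len(K)) {
        lam_k <- matrix(lambda[k, , ], J, L)
        W[, , k] <- g[, k] * matrix(lam_k[obs_idx], N, J)
      }
      tot <- matrix(rowSums(matrix(W, N * J, K)), N, J)
      z <- matrix(1L, N, J)
      if (K > 1L) {
        u <- matrix(stats::runif(N * J), N, J) * tot
        cum <- W[, , 1L]
        for (k in seq_len(K - 1L)) {
          z <- z + (u > cum)
          if (k < K - 1L) cum <- cum + W[, , k + 1L]
        }
      }

      ## g | z, alpha  (conjugate Dirichlet)
      shape <- matrix(alpha0 * rep(xi, each = N), N, K)
      for (k in seq_len(K)) shape[, k] <- shape[, k] + rowSums(z == k)
      gg <- matrix(stats::rgamma(N * K, shape = shape), N, K)
      gg <- pmax(gg, 1e-300)
      g <- gg / rowSums(gg)

      ## lambda | z, Y  (conjugate Dirichlet per profile-item)
      for (k in seq_len(K)) {
        sel <- (z == k)
        counts <- matrix(0, J, L)
        for (l in seq_len(L)) counts[, l] <- colSums(sel & (M == l))
        sh <- counts + config$prior_lambda
        lam <- matrix(stats::rgamma(J * L, shape = sh), J, L)
        lam <- pmax(lam, 1e-300)
        lambda[k, , ] <- lam / rowSums(lam)
      }

      ## (alpha0, xi) | g  (Metropolis within Gibbs)
      if (K > 1L) {
        lp_cur <- ddirichlet_log(g, alpha0 * xi) +
          stats::dgamma(alpha0, config$prior_alpha0_shape,
                        config$prior_alpha0_rate, log = TRUE)
        a_prop <- alpha0 * exp(stats::rnorm(1, 0, config$mh_sd_alpha0))
        lp_prop <- ddirichlet_log(g, a_prop * xi) +
          stats::dgamma(a_prop, config$prior_alpha0_shape,
                        config$prior_alpha0_rate, log = TRUE)
        # log-normal RW: add log-proposal asymmetry via log(a_prop/alpha0)
        if (log(stats::runif(1)) < lp_prop - lp_cur + log(a_prop / alpha0)) {
          alpha0 <- a_prop
        }
        conc <- config$xi_proposal_conc
        xi_prop <- as.numeric(rdirichlet(1L, conc * xi))
        lp_cur <- ddirichlet_log(g, alpha0 * xi) +
          (config$prior_xi - 1) * sum(log(xi))
        lp_prop <- ddirichlet_log(g, alpha0 * xi_prop) +
          (config$prior_xi - 1) * sum(log(xi_prop))
        # Dirichlet proposal is asymmetric; include the Hastings ratio
        q_fwd <- lgamma(conc) - sum(lgamma(conc * xi)) +
          sum((conc * xi - 1) * log(xi_prop))
        q_bwd <- lgamma(conc) - sum(lgamma(conc * xi_prop)) +
          sum((conc * xi_prop - 1) * log(xi))
        if (log(stats::runif(1)) < lp_prop - lp_cur + q_bwd - q_fwd) {
          xi <- xi_prop
        }
      }

      if (it > config$burn_in) {
        d <- it - config$burn_in
        lambda_draws[d, , , ] <- lambda
        g_draws[d, , ] <- g
        xi_draws[d, ] <- xi
        alpha0_draws[d] <- alpha0
        # observed-data log-likelihood at the current (g, lambda)
        p_obs <- matrix(0, N, J)
        for (k in seq_len(K)) {
          lam_k <- matrix(lambda[k, , ], J, L)
          p_obs <- p_obs + g[, k] * matrix(lam_k[obs_idx], N, J)
        }
        loglik[d] <- sum(log(pmax(p_obs, 1e-300)))
      }
    }
  })

  draws <- align_labels(list(lambda = lambda_draws, g = g_draws,
                             xi = xi_draws, loglik = loglik))
  lambda_draws <- draws$lambda; g_draws <- draws$g; xi_draws <- draws$xi

  g_means <- apply(g_draws, c(2, 3), mean)
  dimnames(g_means) <- list(rownames(M), paste0("profile", seq_len(K)))
  lambda_mean <- apply(lambda_draws, c(2, 3, 4), mean)
  dimnames(lambda_mean) <- list(paste0("profile", seq_len(K)),
                                colnames(M), paste0("cat", seq_len(L)))

  rhat <- .split_rhat(loglik)
  if (is.finite(rhat) && rhat > 1.1) {
    warning(sprintf("log-likelihood split-chain R-hat = %.3f (> 1.1): ",
                    rhat), "chain may not have converged", call. = FALSE)
  }

  structure(list(
    K = K, L = L, regions = rownames(M), items = colnames(M),
    lambda_draws = lambda_draws, g_draws = g_draws,
    xi_draws = xi_draws, alpha0_draws = alpha0_draws, loglik = loglik,
    g_means = g_means, lambda_mean = lambda_mean,
    xi = colMeans(xi_draws), alpha0 = mean(alpha0_draws),
    rhat_loglik = rhat, config = config, Y = M
  ), class = "gom_fit")
}

# split-chain potential scale reduction on a scalar trace
.split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 4L) return(NA_real_)
  chains <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  m <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2L, stats::var)
  B <- n * stats::var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(1)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

#' Undo label switching across MCMC draws
#'
#' Per draw, applies the permutation of profile labels minimizing the squared
#' distance of that draw's lambda array to a reference draw (the draw with
#' the highest log-likelihood). Deterministic given the draws; a no-op for
#' K = 1.
#'
#' @param draws list with elements `lambda` (`[draw, K, J, L]`), `g`
#'   (`[draw, N, K]`), `xi` (`[draw, K]`) and `loglik`.
#' @return the same list, relabeled.
#' @export
align_labels <- function(draws) {
  K <- dim(draws$lambda)[2L]
  if (K == 1L) return(draws)
  n_draw <- dim(draws$lambda)[1L]
  ref_i <- if (length(draws$loglik) == n_draw && any(is.finite(draws$loglik)))
    which.max(draws$loglik) else 1L
  ref <- draws$lambda[ref_i, , , , drop = FALSE]
  perms <- permutations(K)
  for (d in seq_len(n_draw)) {
    lam <- draws$lambda[d, , , , drop = FALSE]
    costs <- vapply(perms, function(p)
      sum((lam[, p, , , drop = FALSE] - ref)^2), numeric(1))
    best <- perms[[which.min(costs)]]
    if (!identical(best, seq_len(K))) {
      draws$lambda[d, , , ] <- draws$lambda[d, best, , ]
      draws$g[d, , ] <- draws$g[d, , best]
      draws$xi[d, ] <- draws$xi[d, best]
    }
  }
  draws
}

#' Classify regions into extreme and mixed homoclimatic tiers
#'
#' The dominant profile is `argmax_k g_ik` of the posterior mean memberships;
#' the tier is set by the first membership cutoff met: `extreme`
#' (g >= 0.90), `high-mixed` (0.75 <= g < 0.90), `medium-mixed`
#' (0.50 <= g < 0.75). The binary zone reclassifies mixed tiers to their
#' dominant extreme profile. Exact ties go to the lower profile index with a
#' warning.
#'
#' @param fit a `gom_fit` (or a numeric membership matrix).
#' @param cutoffs descending tier thresholds (default `c(0.90, 0.75, 0.50)`).
#' @return tibble `region_id`, `profile`, `g_max`, `tier`, `zone`.
#' @export
classify_profiles <- function(fit, cutoffs = c(0.90, 0.75, 0.50)) {
  g <- if (inherits(fit, "gom_fit")) fit$g_means else as.matrix(fit)
  stopifnot(ncol(g) >= 2L, all(diff(cutoffs) < 0))
  ties <- apply(g, 1L, function(r) sum(r == max(r)) > 1L)
  if (any(ties)) {
    warning("exact tie in dominant membership for region(s) ",
            paste(rownames(g)[ties], collapse = ", "),
            "; assigned to the lower profile index", call. = FALSE)
  }
  dom <- apply(g, 1L, which.max) # which.max takes the first (lower) index
  g_max <- g[cbind(seq_len(nrow(g)), dom)]
  tier_names <- c("extreme", "high-mixed", "medium-mixed")
  tier <- rep("sub-threshold", nrow(g))
  for (i in rev(seq_along(cutoffs))) tier[g_max >= cutoffs[i]] <- tier_names[i]
  if (any(tier == "sub-threshold")) {
    warning("region(s) below the lowest membership cutoff: ",
            paste(rownames(g)[tier == "sub-threshold"], collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(
    region_id = rownames(g) %||% as.character(seq_len(nrow(g))),
    profile = as.integer(dom), g_max = as.numeric(g_max), tier = tier,
    zone = paste0("profile", dom)
  )
}

#' Salient profile characteristics
#'
#' Flags (item, category) pairs whose posterior mean response probability
#' under a profile is at least `ratio_threshold` times the category's
#' marginal frequency in the observed matrix — the "at least 20% higher than
#' in the overall study region" rule at the default 1.2.
#'
#' @param fit a `gom_fit`.
#' @param Y optional long categorical matrix; defaults to the matrix the
#'   model was fitted to.
#' @param ratio_threshold salience ratio (default 1.2).
#' @return tibble `profile`, `item_id`, `category`, `lambda_mean`,
#'   `marginal`, `ratio`, `salient`.
#' @export
characterize_profiles <- function(fit, Y = NULL, ratio_threshold = 1.2) {
  M <- if (is.null(Y)) fit$Y else .as_response_matrix(Y)
  N <- nrow(M)
  out <- list()
  for (j in seq_along(fit$items)) {
    marg <- tabulate(M[, j], nbins = fit$L) / N
    for (k in seq_len(fit$K)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        profile = k, item_id = fit$items[j], category = seq_len(fit$L),
        lambda_mean = fit$lambda_mean[k, j, ], marginal = marg
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res$ratio <- ifelse(res$marginal > 0, res$lambda_mean / res$marginal, Inf)
  res$salient <- res$marginal > 0 &
    res$lambda_mean >= ratio_threshold * res$marginal
  res
}

#' Name the two profiles as homoclimatic zones
#'
#' With K = 2, labels the profile whose expected R99p category is higher as
#' `"ER"` (extreme rain) and the other as `"ED-HT"` (extreme drought and
#' high temperature). Falls back to the CDD item (reversed) if no `r99p`
#' item is present.
#'
#' @param fit a `gom_fit` with K = 2.
#' @param assignment output of [classify_profiles()].
#' @return `assignment` with an added `zone_binary` column in
#'   `c("ER", "ED-HT")`.
#' @export
label_zones <- function(fit, assignment) {
  stopifnot(fit$K == 2L)
  pick <- function(item, reverse = FALSE) {
    j <- match(item, fit$items)
    sc <- vapply(1:2, function(k)
      sum(seq_len(fit$L) * fit$lambda_mean[k, j, ]), numeric(1))
    if (reverse) which.min(sc) else which.max(sc)
  }
  er <- if ("r99p" %in% fit$items) pick("r99p")
        else if ("cdd" %in% fit$items) pick("cdd", reverse = TRUE)
        else 1L
  labels <- c("ED-HT", "ED-HT"); labels[er] <- "ER"
  assignment$zone_binary <- labels[assignment$profile]
  assignment
}
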