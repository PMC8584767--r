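# Independent brute-force oracles. These deliberately use explicit loops,
# sorting and first-principles definitions so they share no code with the
# implementation they check.

# q-th percentile by explicit sort + linear interpolation (type-7 rule)
oracle_percentile <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# longest run of dry days (precip < thr) per year, then mean of annual maxima
oracle_cdd <- function(dates, precip, thr = 1.0) {
  years <- as.integer(format(dates, "%Y"))
  annual <- sapply(unique(years), function(y) {
    p <- precip[years == y]
    best <- 0L; run <- 0L
    for (d in seq_along(p)) {
      if (!is.na(p[d]) && p[d] < thr) run <- run + 1L else run <- 0L
      if (run > best) best <- run
    }
    best
  })
  mean(annual)
}

# wet-day 99th percentile threshold, then mean annual total above it
oracle_r99p <- function(dates, precip, q = 99, wet_thr = 1.0) {
  wet <- precip[!is.na(precip) & precip >= wet_thr]
  thr <- oracle_percentile(wet, q / 100)
  years <- as.integer(format(dates, "%Y"))
  annual <- sapply(unique(years), function(y) {
    p <- precip[years == y]
    sum(p[!is.na(p) & p > thr])
  })
  mean(annual)
}

# per-calendar-day threshold by explicit collection over a centered window,
# then an explicit exceedance count
oracle_tx90p <- function(dates, values, q = 90, window = 5L) {
  doy <- as.integer(as.Date(paste0("2000-", format(dates, "%m-%d")))) -
    as.integer(as.Date("2000-01-01")) + 1L
  half <- (window - 1L) %/% 2L
  thr <- rep(NA_real_, 366L)
  for (d in unique(doy)) {
    vals <- c()
    for (i in seq_along(dates)) {
      dist <- abs(doy[i] - d)
      dist <- min(dist, 366L - dist)
      if (dist <= half && !is.na(values[i])) vals <- c(vals, values[i])
    }
    if (length(vals) > 0L) thr[d] <- oracle_percentile(vals, q / 100)
  }
  n_ok <- 0L; n_ex <- 0L
  for (i in seq_along(values)) {
    if (is.na(values[i])) next
    n_ok <- n_ok + 1L
    if (!is.na(thr[doy[i]]) && values[i] > thr[doy[i]]) n_ex <- n_ex + 1L
  }
  100 * n_ex / n_ok
}

# Alkire-Foster from first principles: loops over regions, counting
# definition on a flag matrix (regions x indicators) with weights.
oracle_af <- function(flags, weights, pops, k_p) {
  n <- nrow(flags)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(flags))) c_i[i] <- c_i[i] + weights[j] * flags[i, j]
  }
  vul <- c_i >= k_p
  ch <- sum(pops[vul]) / sum(pops)
  di <- if (any(vul)) sum(pops[vul] * c_i[vul]) / sum(pops[vul]) else 0
  # indicator decomposition from first principles
  ch_ind <- numeric(ncol(flags))
  for (j in seq_len(ncol(flags))) {
    ch_ind[j] <- sum(pops * flags[, j] * vul) / sum(pops)
  }
  list(ch = ch, di = di, ecvi = ch * di, c_i = c_i, ch_ind = ch_ind)
}

# brute-force forward-window population variances
oracle_window_var <- function(values, t) {
  out <- rep(NA_real_, length(values))
  for (p in seq_along(values)) {
    if (p + t - 1 > length(values)) next
    w <- values[p:(p + t - 1)]
    m <- sum(w) / t
    out[p] <- sum((w - m)^2) / t
  }
  out
}

# --- fixture builders -------------------------------------------------------

make_series <- function(region_id = "A", start = "2001-01-01", n_days = 365,
                        tmax = 30, tmin = 20, precip = 0) {
  dates <- seq(as.Date(start), by = "day", length.out = n_days)
  tibble::tibble(
    region_id = region_id, date = dates,
    tmax = rep_len(tmax, n_days), tmin = rep_len(tmin, n_days),
    precip = rep_len(precip, n_days)
  )
}

# a sinusoidal 2-year series with reproducible noise and rain
make_weather <- function(region_id = "A", seed = 42, n_years = 2) {
  set.seed(seed)
  dates <- seq(as.Date("2001-01-01"), by = "day",
               length.out = 365 * n_years)
  doy <- as.integer(format(dates, "%j"))
  tmax <- 30 + 4 * sin(2 * pi * doy / 365) + rnorm(length(dates), 0, 1.5)
  tmin <- tmax - pmax(0.5, 8 + rnorm(length(dates), 0, 1))
  precip <- ifelse(runif(length(dates)) < 0.4,
                   rgamma(length(dates), 1.2, scale = 8) + 1, 0)
  tibble::tibble(region_id = region_id, date = dates, tmax = tmax,
                 tmin = tmin, precip = precip)
}

# small random deprivation panels for property tests
random_score_panel <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    region_id = sprintf("S%02d", seq_len(n)),
    score = round(runif(n), 3),
    population = exp(rnorm(n, 12, 0.5))
  )
}

# fixed-seed Dirichlet memberships (rows on the simplex)
rdir_fixture <- function(n, alpha, seed) {
  set.seed(seed)
  x <- matrix(rgamma(n * length(alpha), rep(alpha, each = n)), n)
  x / rowSums(x)
}

# sample categorical data from a known GoM (mixed-membership) model
sample_gom_data <- function(g, lambda, seed) {
  set.seed(seed)
  N <- nrow(g); K <- ncol(g); J <- dim(lambda)[2]; L <- dim(lambda)[3]
  rows <- list()
  for (i in seq_len(N)) {
    for (j in seq_len(J)) {
      k <- sample.int(K, 1L, prob = g[i, ])
      l <- sample.int(L, 1L, prob = lambda[k, j, ])
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = sprintf("G%03d", i), item_id = sprintf("item%d", j),
        category = l)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# the well-separated two-profile design: profile 1 loads on low categories,
# profile 2 on high categories, J = 7 items, L = 5
separated_lambda <- function(J = 7, L = 5, eps = 0.02) {
  lam <- array(eps / (L - 2), c(2, J, L))
  for (j in seq_len(J)) {
    lam[1, j, 1:2] <- (1 - eps) / 2
    lam[2, j, (L - 1):L] <- (1 - eps) / 2
    lam[1, j, 3:L] <- eps / 3
    lam[2, j, 1:3] <- eps / 3
  }
  lam
}
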