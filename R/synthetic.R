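#' Synthetic studies with known ground truth
#'
#' Generates complete synthetic studies emulating the structure of the real
#' inputs — daily per-region weather, a region-level indicator panel with
#' populations, and annual counts of climate-sensitive hospitalizations —
#' from two latent climate regimes: an extreme-rain (ER-like) regime with
#' frequent wet days, heavy-tailed rain events and cooler maxima, and a
#' drought/heat (ED-HT-like) regime with long dry runs, hotter maxima and a
#' wider diurnal range. Region memberships in the two regimes are Dirichlet
#' draws, daily weather mixes the regime generators by membership,
#' socioeconomic indicators shift with the dominant regime, and disease
#' counts are Poisson with a log-rate linear in the region's weighted
#' deprivation score. Everything is seeded: a fixed master seed gives
#' bit-identical output.
#'
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' Defaults are sized to the study design: 62 regions and 34 years of daily
#' data, with membership spread `alpha0 = 0.5` (clear-cut profiles) and
#' equal expected proportions. The `"fast"` profile (30 regions, 3 years)
#' keeps full end-to-end runs at desk scale.
#'
#' @param profile `"study"` (62 regions, 34 years) or `"fast"` (30 regions,
#'   3 years).
#' @param n_regions,years,start_year study dimensions (override the
#'   profile).
#' @param alpha0,xi Dirichlet membership parameters (`alpha = alpha0 * xi`).
#' @param regimes list of two regime parameter lists (`er`, `edht`), each
#'   with Markov-chain rain parameters (`p_wd` dry-to-wet, `p_ww`
#'   wet-to-wet), gamma wet-day amounts (`rain_shape`, `rain_scale`), a
#'   heavy-event mixture (`heavy_rate`, `heavy_scale`), and temperature
#'   parameters (`tmax_mean`, `season_amp`, `dtr_mean`, `noise_sd`).
#' @param indicator_effects named effects added to ED-HT-dominant regions'
#'   non-climate indicators (sign set so ED-HT is worse off by default).
#' @param indicator_noise_sd noise SD for non-climate indicators.
#' @param pop_meanlog,pop_sdlog log-normal population parameters.
#' @param disease_beta0 log baseline hospitalization rate per 100,000.
#' @param disease_beta1 log-rate increase per unit weighted deprivation
#'   score.
#' @param seed master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(profile = c("study", "fast"),
                             n_regions = NULL, years = NULL,
                             start_year = 1980L,
                             alpha0 = 0.5, xi = c(0.5, 0.5),
                             regimes = NULL,
                             indicator_effects = NULL,
                             indicator_noise_sd = 0.05,
                             pop_meanlog = log(3e5), pop_sdlog = 0.6,
                             disease_beta0 = log(400),
                             disease_beta1 = 2.5,
                             seed = 1L) {
  profile <- match.arg(profile)
  n_regions <- n_regions %||% if (profile == "study") 62L else 30L
  years <- years %||% if (profile == "study") 34L else 3L
  regimes <- regimes %||% list(
    er = list(p_wd = 0.50, p_ww = 0.75, rain_shape = 1.2, rain_scale = 9,
              heavy_rate = 0.02, heavy_scale = 60,
              tmax_mean = 30, season_amp = 2.5, dtr_mean = 7,
              noise_sd = 1.2),
    edht = list(p_wd = 0.06, p_ww = 0.45, rain_shape = 1.0, rain_scale = 6,
                heavy_rate = 0.002, heavy_scale = 40,
                tmax_mean = 35, season_amp = 3.5, dtr_mean = 11,
                noise_sd = 1.2)
  )
  indicator_effects <- indicator_effects %||% c(
    prop_elderly = 0.02, prop_children = 0.02, income_per_capita = -120,
    prop_poor = 0.10, prop_literate = -0.08,
    prop_sewage = -0.15, prop_water = -0.12, prop_garbage = -0.15,
    urbanization = -0.12, primary_care = -0.10, hospital_beds = -60
  )
  stopifnot(alpha0 > 0, abs(sum(xi) - 1) < 1e-9, all(xi > 0),
            n_regions >= 2L, years >= 1L)
  structure(list(profile = profile, n_regions = as.integer(n_regions),
                 years = as.integer(years), start_year = as.integer(start_year),
                 alpha0 = alpha0, xi = xi, regimes = regimes,
                 indicator_effects = indicator_effects,
                 indicator_noise_sd = indicator_noise_sd,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 disease_beta0 = disease_beta0,
                 disease_beta1 = disease_beta1,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.region_ids <- function(n) sprintf("R%03d", seq_len(n))

#' True regime memberships
#'
#' Draws `g_i ~ Dirichlet(alpha0 * xi)` per region: the ground truth that
#' recovery tests compare the fitted memberships against. Column 1 is the
#' ER-like regime, column 2 the ED-HT-like regime.
#'
#' @param config a [synthetic_config()].
#' @return numeric matrix regions x 2 with rownames.
#' @export
generate_memberships <- function(config) {
  stopifnot(length(config$xi) == 2L)
  g <- with_seed(derive_seed(config$seed, "memberships"),
                 rdirichlet(config$n_regions, config$alpha0 * config$xi))
  rownames(g) <- .region_ids(config$n_regions)
  colnames(g) <- c("er", "edht")
  g
}

# mix two regime parameter lists by membership weights
.mix_params <- function(regimes, g_row) {
  er <- regimes$er; ed <- regimes$edht
  out <- lapply(names(er), function(nm) g_row[1L] * er[[nm]] +
                  g_row[2L] * ed[[nm]])
  stats::setNames(out, names(er))
}

#' Daily weather series from the regime mixture
#'
#' Per region, parameters are the membership-weighted mixture of the two
#' regime generators. Precipitation follows a two-state (wet/dry) Markov
#' chain with gamma wet-day amounts plus rare exponential heavy events;
#' temperatures are a seasonal sinusoid plus regime mean shift and Gaussian
#' noise, with `tmin = tmax - diurnal range` (range floored at 0.5 C so
#' `tmax > tmin` always holds).
#'
#' @param config a [synthetic_config()].
#' @param memberships matrix from [generate_memberships()].
#' @return a daily series tibble (`region_id`, `date`, `tmax`, `tmin`,
#'   `precip`).
#' @export
generate_daily_climate <- function(config, memberships) {
  start <- as.Date(sprintf("%d-01-01", config$start_year))
  end <- as.Date(sprintf("%d-12-31", config$start_year + config$years - 1L))
  dates <- seq(start, end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  n_day <- length(dates)
  out <- vector("list", nrow(memberships))
  for (i in seq_len(nrow(memberships))) {
    id <- rownames(memberships)[i]
    p <- .mix_params(config$regimes, memberships[i, ])
    out[[i]] <- with_seed(derive_seed(config$seed, paste0("climate-", id)), {
      wet <- logical(n_day)
      u <- stats::runif(n_day)
      wet[1L] <- u[1L] < p$p_wd
      for (d in 2L:n_day) {
        wet[d] <- u[d] < if (wet[d - 1L]) p$p_ww else p$p_wd
      }
      precip <- numeric(n_day)
      nw <- sum(wet)
      if (nw > 0L) {
        amt <- stats::rgamma(nw, shape = p$rain_shape,
                             scale = p$rain_scale) + 1
        heavy <- stats::runif(nw) < p$heavy_rate
        amt[heavy] <- amt[heavy] + stats::rexp(sum(heavy), 1 / p$heavy_scale)
        precip[wet] <- amt
      }
      season <- p$season_amp * sin(2 * pi * (doy - 30) / 365.25)
      tmax <- p$tmax_mean + season + stats::rnorm(n_day, 0, p$noise_sd)
      dtr <- pmax(0.5, p$dtr_mean + stats::rnorm(n_day, 0, 0.5))
      tibble::tibble(region_id = id, date = dates, tmax = tmax,
                     tmin = tmax - dtr, precip = precip)
    })
  }
  dplyr::bind_rows(out)
}

#' Region-level socioeconomic indicator panel
#'
#' Each non-climate indicator is `baseline + effect x I(dominant regime is
#' ED-HT) + noise`, with the default effect signs making the ED-HT-like
#' zone worse off (poorer, less literate, weaker infrastructure);
#' proportions are clamped to `[0.01, 0.99]`. Populations are log-normal.
#'
#' @inheritParams generate_daily_climate
#' @return tibble `region_id`, `population`, `true_zone`, and the 11
#'   susceptibility / adaptive-capacity indicator columns (climate exposure
#'   indicators come from the daily series via
#'   [compute_climate_indices()]).
#' @export
generate_indicator_panel <- function(config, memberships) {
  baselines <- c(
    prop_elderly = 0.10, prop_children = 0.09, income_per_capita = 500,
    prop_poor = 0.35, prop_literate = 0.82,
    prop_sewage = 0.55, prop_water = 0.75, prop_garbage = 0.70,
    urbanization = 0.60, primary_care = 0.70, hospital_beds = 220
  )
  scale_of <- c(prop_elderly = 1, prop_children = 1, income_per_capita = 2000,
                prop_poor = 1, prop_literate = 1, prop_sewage = 1,
                prop_water = 1, prop_garbage = 1, urbanization = 1,
                primary_care = 1, hospital_beds = 2000)
  dominant_edht <- as.numeric(memberships[, "edht"] >= memberships[, "er"])
  n <- nrow(memberships)
  with_seed(derive_seed(config$seed, "panel"), {
    panel <- tibble::tibble(
      region_id = rownames(memberships),
      population = stats::rlnorm(n, config$pop_meanlog, config$pop_sdlog),
      true_zone = ifelse(dominant_edht == 1, "ED-HT", "ER")
    )
    for (nm in names(baselines)) {
      eff <- if (nm %in% names(config$indicator_effects))
        config$indicator_effects[[nm]] else 0
      v <- baselines[[nm]] + eff * dominant_edht +
        stats::rnorm(n, 0, config$indicator_noise_sd * scale_of[[nm]])
      if (scale_of[[nm]] == 1) v <- pmin(pmax(v, 0.01), 0.99)
      else v <- pmax(v, 1)
      panel[[nm]] <- v
    }
    panel
  })
}

#' Annual climate-sensitive hospitalization counts
#'
#' Five annual counts per region, `count ~ Poisson(pop x rate / 1e5)` with
#' `log(rate) = beta0 + beta1 x c_i`, where `c_i` is the region's weighted
#' deprivation score under the default schema — so disease incidence rises
#' with multidimensional deprivation when `beta1 > 0`.
#'
#' @param config a [synthetic_config()].
#' @param panel full indicator panel (climate + socioeconomic columns).
#' @param schema deprivation schema (default [ecvi_schema()]).
#' @param n_years number of annual counts (default 5).
#' @return tibble `region_id`, `year`, `count`.
#' @export
generate_disease_counts <- function(config, panel, schema = ecvi_schema(),
                                    n_years = 5L) {
  dep <- apply_deprivation_cutoffs(panel, schema)
  scores <- weighted_score(dep, schema)
  rate <- exp(config$disease_beta0 +
                config$disease_beta1 *
                  scores$score[match(panel$region_id, scores$region_id)])
  with_seed(derive_seed(config$seed, "disease"), {
    out <- lapply(seq_len(n_years), function(y) {
      tibble::tibble(region_id = panel$region_id, year = y,
                     count = stats::rpois(nrow(panel),
                                          panel$population * rate / 1e5))
    })
    dplyr::bind_rows(out)
  })
}

#' Generate a complete synthetic study
#'
#' Bundles all generator stages: true memberships, daily climate, climate
#' indices, the full 18-indicator panel and disease counts.
#'
#' @param config a [synthetic_config()].
#' @return list with `config`, `memberships`, `climate`, `indices`,
#'   `panel` (socio + climate indicators), `counts`.
#' @export
generate_study <- function(config = synthetic_config()) {
  memberships <- generate_memberships(config)
  climate <- generate_daily_climate(config, memberships)
  indices <- compute_climate_indices(climate)
  socio <- generate_indicator_panel(config, memberships)
  panel <- dplyr::left_join(socio, indices, by = "region_id")
  counts <- generate_disease_counts(config, panel)
  list(config = config, memberships = memberships, climate = climate,
       indices = indices, panel = panel, counts = counts)
}
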