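#' End-to-end pipeline
#'
#' Orchestrates the full analysis on a synthetic study: daily climate ->
#' extreme indices -> quintile coding -> Grade of Membership zoning ->
#' population-weighted ECVI (overall, by zone, by zone x disease-incidence
#' stratum) with decompositions -> cutoff-selection diagnostics; optionally
#' serializes every table plus a JSON run manifest (config, seeds, stage row
#' counts) sufficient to reproduce the run.
#'
#' @name pipeline
NULL

#' Disease rate per 100,000 from annual counts
#'
#' `rate = mean(annual counts) / population x 100,000`, the 5-year-average
#' convention against a single reference population.
#'
#' @param counts numeric vector of annual counts (length 5 by convention).
#' @param population reference population (> 0).
#' @param n_years required number of annual counts (default 5).
#' @return rate per 100,000 inhabitants.
#' @export
disease_rate <- function(counts, population, n_years = 5L) {
  if (length(counts) != n_years) {
    stop("expected exactly ", n_years, " annual counts")
  }
  if (any(counts < 0)) stop("negative counts")
  if (population <= 0) stop("population must be positive")
  mean(counts) / population * 1e5
}

#' Disease rates for a full panel
#'
#' @param counts long tibble `region_id`, `year`, `count`.
#' @param panel tibble with `region_id`, `population`.
#' @inheritParams disease_rate
#' @return tibble `region_id`, `rate`.
#' @export
disease_rates <- function(counts, panel, n_years = 5L) {
  counts |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(rate = disease_rate(
      .data$count,
      panel$population[match(.data$region_id[1L], panel$region_id)],
      n_years), .groups = "drop")
}

#' Incidence strata from disease rates
#'
#' Quintiles the rate distribution (rank-based, stable region_id
#' tie-break): the first quintile is the `low` stratum, the fourth and
#' fifth quintiles the `high` stratum, quintiles 2-3 the `middle` stratum
#' (excluded from the stratified low-vs-high comparison). All-equal rates
#' degenerate to quintile 1 (`low`) with a warning.
#'
#' @param rates tibble `region_id`, `rate` (>= 5 regions).
#' @return tibble `region_id`, `rate`, `quintile`, `stratum`.
#' @export
incidence_strata <- function(rates) {
  if (nrow(rates) < 5L) stop("need at least 5 regions to form quintiles")
  if (length(unique(rates$rate)) == 1L) {
    warning("all rates equal; every region assigned to quintile 1",
            call. = FALSE)
    q <- rep(1L, nrow(rates))
  } else {
    if (anyDuplicated(rates$rate) > 0L) {
      warning("ties in rates; quintiles assigned by rank with stable ",
              "region_id tie-break", call. = FALSE)
    }
    q <- rank_ntile(rates$rate, 5L, tie_key = rates$region_id)
  }
  rates$quintile <- q
  rates$stratum <- dplyr::case_when(q == 1L ~ "low",
                                    q >= 4L ~ "high",
                                    TRUE ~ "middle")
  rates
}

#' Run the full pipeline on a synthetic study
#'
#' @param config a [synthetic_config()]; its seed drives every stage.
#' @param k_p chosen multidimensional cutoff (default 0.25).
#' @param gom a [gom_config()]; its seed defaults to one derived from the
#'   study seed.
#' @param schema deprivation schema (default [ecvi_schema()]).
#' @param se_method standard-error method for the headline tables.
#' @param kp_grid,kp_t cutoff-diagnostic grid and window length.
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV plus a `manifest.json`.
#' @return list with the study bundle, the GoM fit and zone assignment, the
#'   headline ECVI table by zone (`table_zones`), by zone x incidence
#'   stratum (`table_strata`), subgroup/indicator/dimension decompositions,
#'   the cutoff report and the manifest.
#' @export
run_pipeline <- function(config = synthetic_config("fast"), k_p = 0.25,
                         gom = NULL, schema = ecvi_schema(),
                         se_method = "bootstrap",
                         kp_grid = seq(0.05, 1, by = 0.05), kp_t = 3L,
                         out_dir = NULL) {
  study <- generate_study(config)
  categories <- categorize_quantiles(study$indices)
  gom <- gom %||% gom_config(seed = derive_seed(config$seed, "gom"))
  fit <- fit_gom(categories, gom)
  assignment <- label_zones(fit, classify_profiles(fit))
  zones <- assignment[c("region_id", "zone_binary")]
  names(zones)[2L] <- "group"

  panel <- study$panel
  dep <- apply_deprivation_cutoffs(panel, schema)
  scores <- weighted_score(dep, schema)
  pops <- panel[c("region_id", "population")]

  with_se <- se_method != "none"
  overall <- compute_ecvi(scores, pops, k_p, se = se_method,
                          seed = derive_seed(config$seed, "se"))
  by_zone <- decompose_by_subgroup(scores, pops, zones, k_p)
  est_cols <- c("ch", "di", "ecvi",
                if (with_se) c("ch_se", "di_se", "ecvi_se"))
  table_zones <- dplyr::bind_cols(
    tibble::tibble(group = "overall", population_share = 1),
    overall[intersect(est_cols, names(overall))]
  )
  if (with_se) {
    zone_se <- lapply(unique(zones$group), function(g) {
      ids <- zones$region_id[zones$group == g]
      estimate_se(scores[scores$region_id %in% ids, ], pops, k_p,
                  method = se_method,
                  seed = derive_seed(config$seed, paste0("se-", g)))
    })
    by_zone <- dplyr::bind_cols(by_zone, dplyr::bind_rows(zone_se))
  }
  table_zones <- dplyr::bind_rows(table_zones, by_zone)

  rates <- incidence_strata(disease_rates(study$counts, panel))
  strata <- rates[c("region_id", "stratum")]
  table_strata <- list()
  for (s in c("low", "high")) {
    ids <- strata$region_id[strata$stratum == s]
    if (length(ids) == 0L) next
    sub <- scores[scores$region_id %in% ids, ]
    strat_row <- function(sc, s, g, stream) {
      r <- compute_ecvi(sc, pops, k_p, se = se_method,
                        seed = derive_seed(config$seed, stream))
      dplyr::bind_cols(tibble::tibble(stratum = s, group = g),
                       r[intersect(est_cols, names(r))])
    }
    rows <- strat_row(sub, s, "overall", paste0("se-", s))
    for (g in unique(zones$group)) {
      gid <- intersect(ids, zones$region_id[zones$group == g])
      if (length(gid) == 0L) next
      rows <- dplyr::bind_rows(
        rows, strat_row(scores[scores$region_id %in% gid, ], s, g,
                        paste0("se-", s, "-", g)))
    }
    table_strata[[s]] <- rows
  }
  table_strata <- dplyr::bind_rows(table_strata)

  decomp_ind <- decompose_by_indicator(dep, pops, k_p, schema)
  report <- kp_report(scores, pops, partition = zones, grid = kp_grid,
                      t = kp_t, chosen_kp = k_p)

  manifest <- list(
    seed = config$seed, profile = config$profile,
    n_regions = config$n_regions, years = config$years,
    k_p = k_p, se_method = se_method, kp_t = kp_t,
    gom = unclass(gom),
    stage_rows = list(climate = nrow(study$climate),
                      indices = nrow(study$indices),
                      categories = nrow(categories),
                      panel = nrow(panel),
                      counts = nrow(study$counts)),
    rhat_loglik = fit$rhat_loglik
  )

  result <- list(study = study, categories = categories, fit = fit,
                 assignment = assignment, deprivation = dep,
                 scores = scores, rates = rates,
                 table_zones = table_zones, table_strata = table_strata,
                 decomposition = decomp_ind, kp_report = report,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
    w(study$indices, "climate_indices.csv")
    w(categories, "category_matrix.csv")
    w(tibble::as_tibble(fit$g_means, rownames = "region_id"),
      "memberships.csv")
    w(assignment, "zone_assignment.csv")
    w(table_zones, "ecvi_by_zone.csv")
    if (nrow(table_strata) > 0L) w(table_strata, "ecvi_by_stratum.csv")
    w(decomp_ind$indicator, "decomposition_indicator.csv")
    w(decomp_ind$dimension, "decomposition_dimension.csv")
    w(report$curves, "kp_curves.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
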