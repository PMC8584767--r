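#' Alkire-Foster Extreme Climate Vulnerability Index
#'
#' The ECVI is the adjusted-headcount (M0-style) index of the dual-cutoff
#' Alkire-Foster family. Each region gets a weighted deprivation score
#' `c_i = sum_i w_i * flag_i` from 18 indicators in three equally weighted
#' dimensions (exposure, susceptibility, adaptive capacity). A region is
#' vulnerable when `c_i >= k_p`. Then, population-weighted:
#' censored headcount `CH = share of population in vulnerable regions`,
#' deprivation intensity `DI = average censored score among the vulnerable`,
#' and `ECVI = CH x DI` exactly. Both decompositions are exact: by subgroup
#' (`ECVI = sum_g (n_g/n) ECVI_g`) and by indicator
#' (`ECVI = sum_i w_i CH_i` with `CH_i` the censored per-indicator
#' headcount).
#'
#' @name ecvi_index
NULL

#' Default 18-indicator deprivation schema
#'
#' Encodes the study's indicator structure: 7 exposure indicators (the
#' extreme climate indices; deprived when the value is at or above the lower
#' bound of its fourth quartile), 5 susceptibility indicators (elderly,
#' children and poverty shares deprived in the fourth quartile; per capita
#' income deprived below an absolute threshold; adult literacy deprived at
#' or below the first quartile) and 6 adaptive-capacity indicators (deprived
#' at or below the first quartile). Weights are equal within dimension and
#' sum to 1/3 per dimension: 1/21, 1/15 and 1/18.
#'
#' @param income_cutoff absolute monthly per capita income threshold in
#'   2010 BRL. Default 296.8; `255.00` (half the 2010 minimum wage) is the
#'   alternative preset.
#' @return tibble `indicator_id`, `dimension`, `rule` (one of
#'   `"upper_quartile"`, `"lower_quartile"`, `"absolute_below"`),
#'   `threshold`, `weight`.
#' @export
ecvi_schema <- function(income_cutoff = 296.8) {
  exposure <- c("txx", "tnx", "tx90p", "tn90p", "dtr", "cdd", "r99p")
  susceptibility <- c("prop_elderly", "prop_children", "income_per_capita",
                      "prop_poor", "prop_literate")
  adaptive <- c("prop_sewage", "prop_water", "prop_garbage", "urbanization",
                "primary_care", "hospital_beds")
  tibble::tibble(
    indicator_id = c(exposure, susceptibility, adaptive),
    dimension = rep(c("exposure", "susceptibility", "adaptive_capacity"),
                    c(7L, 5L, 6L)),
    rule = c(rep("upper_quartile", 7L),
             "upper_quartile", "upper_quartile", "absolute_below",
             "upper_quartile", "lower_quartile",
             rep("lower_quartile", 6L)),
    threshold = c(rep(NA_real_, 9L), income_cutoff, NA_real_, NA_real_,
                  rep(NA_real_, 6L)),
    weight = rep(c(1 / 21, 1 / 15, 1 / 18), c(7L, 5L, 6L))
  )
}

.check_schema <- function(schema) {
  stopifnot(all(c("indicator_id", "dimension", "rule", "weight") %in%
                  names(schema)))
  if (abs(sum(schema$weight) - 1) > 1e-9) {
    stop("schema weights must sum to 1 (got ", sum(schema$weight), ")")
  }
  invisible(schema)
}

#' Flag per-indicator deprivations against the schema cutoffs
#'
#' Quartile bounds are computed once over the full study area (never per
#' subgroup — required for the subgroup decomposition identity) with
#' inclusive bounds: `upper_quartile` flags `value >= Q3`, `lower_quartile`
#' flags `value <= Q1`, `absolute_below` flags `value < threshold` (strict,
#' so a region exactly at the income cutoff is not deprived).
#'
#' @param panel wide tibble with `region_id` and one numeric column per
#'   schema indicator.
#' @param schema an [ecvi_schema()]-style tibble.
#' @return long tibble `region_id`, `indicator_id`, `deprived` (0/1), with
#'   the schema attached as attribute `"schema"`.
#' @export
apply_deprivation_cutoffs <- function(panel, schema = ecvi_schema()) {
  .check_schema(schema)
  if (nrow(panel) < 4L) stop("need at least 4 regions to define quartiles")
  out <- lapply(seq_len(nrow(schema)), function(r) {
    id <- schema$indicator_id[r]
    if (!id %in% names(panel)) stop("panel is missing indicator ", id)
    v <- panel[[id]]
    if (anyNA(v)) {
      stop("missing value for indicator ", id, " in region(s) ",
           paste(panel$region_id[is.na(v)], collapse = ", "))
    }
    flag <- switch(schema$rule[r],
      upper_quartile = {
        q3 <- ecvi_quantile(v, 0.75)
        if (length(unique(v)) == 1L) {
          warning("indicator ", id, " constant across regions: ",
                  "upper-quartile rule flags every region", call. = FALSE)
        }
        v >= q3
      },
      lower_quartile = v <= ecvi_quantile(v, 0.25),
      absolute_below = v < schema$threshold[r],
      stop("unknown deprivation rule: ", schema$rule[r])
    )
    tibble::tibble(region_id = panel$region_id, indicator_id = id,
                   deprived = as.integer(flag))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "schema") <- schema
  res
}

#' Weighted deprivation score per region
#'
#' `c_i = sum_i w_i * flag_i`, in `[0, 1]`.
#'
#' @param dep long deprivation matrix from [apply_deprivation_cutoffs()].
#' @param schema schema with weights; defaults to the one attached to `dep`.
#' @return tibble `region_id`, `score`.
#' @export
weighted_score <- function(dep, schema = attr(dep, "schema")) {
  .check_schema(schema)
  w <- stats::setNames(schema$weight, schema$indicator_id)
  s <- rowsum(dep$deprived * w[as.character(dep$indicator_id)],
              dep$region_id)
  tibble::tibble(region_id = rownames(s), score = as.numeric(s))
}

# normalize inputs: accept a long deprivation matrix or a ready score table
.as_scores <- function(dep, schema = NULL) {
  if ("score" %in% names(dep)) return(dep[c("region_id", "score")])
  weighted_score(dep, schema %||% attr(dep, "schema"))
}

#' Compute the ECVI and its components
#'
#' Population-weighted censored headcount, deprivation intensity and their
#' product. With `populations` all equal this reduces to the region-counting
#' definitions.
#'
#' @param dep long deprivation matrix, or a tibble with `region_id` and a
#'   precomputed `score` column.
#' @param populations named numeric vector (names = region ids) or a tibble
#'   `region_id`, `population`. Use `rep(1, n)` semantics via
#'   `weighted = FALSE`.
#' @param k_p multidimensional cutoff in `(0, 1]` (default 0.25).
#' @param schema needed only when `dep` carries raw flags without an
#'   attached schema.
#' @param weighted if `FALSE`, ignore populations and count regions.
#' @param se one of `"none"`, `"bootstrap"`, `"linearization"`; when not
#'   `"none"`, standard errors from [estimate_se()] are attached.
#' @param B,seed bootstrap replicates and seed, passed to [estimate_se()].
#' @return tibble with one row: `ch`, `di`, `ecvi`, `n_regions`,
#'   `n_vulnerable`, `vulnerable_share` and, when requested, `ch_se`,
#'   `di_se`, `ecvi_se`.
#' @export
compute_ecvi <- function(dep, populations, k_p = 0.25, schema = NULL,
                         weighted = TRUE, se = c("none", "bootstrap",
                                                 "linearization"),
                         B = 1000L, seed = 1L) {
  se <- match.arg(se)
  stopifnot(k_p > 0, k_p <= 1)
  scores <- .as_scores(dep, schema)
  if (nrow(scores) == 0L) stop("no regions")
  pop <- .match_populations(populations, scores$region_id, weighted)
  est <- .ecvi_point(scores$score, pop, k_p)
  out <- tibble::tibble(
    ch = est[["ch"]], di = est[["di"]], ecvi = est[["ecvi"]],
    n_regions = nrow(scores), n_vulnerable = as.integer(est[["n_vul"]]),
    vulnerable_share = est[["vul_share"]]
  )
  if (se != "none") {
    ses <- estimate_se(scores, pop, k_p, method = se, B = B, seed = seed)
    out$ch_se <- ses$ch_se; out$di_se <- ses$di_se; out$ecvi_se <- ses$ecvi_se
  }
  out
}

.match_populations <- function(populations, region_ids, weighted = TRUE) {
  if (!weighted) return(stats::setNames(rep(1, length(region_ids)), region_ids))
  if (is.data.frame(populations)) {
    populations <- stats::setNames(populations$population,
                                   populations$region_id)
  }
  if (is.null(names(populations))) {
    stopifnot(length(populations) == length(region_ids))
    populations <- stats::setNames(populations, region_ids)
  }
  pop <- populations[as.character(region_ids)]
  if (anyNA(pop)) stop("population missing for region(s) ",
                       paste(region_ids[is.na(pop)], collapse = ", "))
  if (any(pop <= 0)) stop("populations must be positive")
  as.numeric(pop)
}

# point estimates from scores + populations
.ecvi_point <- function(score, pop, k_p) {
  vul <- score >= k_p
  ch <- sum(pop * vul) / sum(pop)
  di <- if (any(vul)) sum(pop * score * vul) / sum(pop * vul) else 0
  c(ch = ch, di = di, ecvi = ch * di, n_vul = sum(vul),
    vul_share = mean(vul))
}

#' Subgroup decomposition of the ECVI
#'
#' Splits the study area by a partition (e.g. homoclimatic zone) and reports
#' each subgroup's ECVI on the pooled deprivation flags (cutoffs are never
#' re-estimated within subgroups), its population share and its contribution
#' `(n_g/n) x ECVI_g / ECVI`. The population-share-weighted subgroup ECVIs
#' sum exactly to the pooled ECVI.
#'
#' @inheritParams compute_ecvi
#' @param partition tibble `region_id`, `group` covering every region
#'   exactly once.
#' @return tibble `group`, `population_share`, `ch`, `di`, `ecvi`,
#'   `contribution` (`NA` when the pooled ECVI is 0).
#' @export
decompose_by_subgroup <- function(dep, populations, partition, k_p = 0.25,
                                  schema = NULL, weighted = TRUE) {
  scores <- .as_scores(dep, schema)
  if (anyDuplicated(partition$region_id) > 0L ||
      !setequal(partition$region_id, scores$region_id)) {
    stop("partition must cover every region exactly once")
  }
  pop <- .match_populations(populations, scores$region_id, weighted)
  total <- .ecvi_point(scores$score, pop, k_p)
  grp <- partition$group[match(scores$region_id, partition$region_id)]
  vul <- scores$score >= k_p
  pg <- rowsum(pop, grp)
  pv <- rowsum(pop * vul, grp)
  psv <- rowsum(pop * scores$score * vul, grp)
  ch <- as.numeric(pv / pg)
  di <- as.numeric(ifelse(pv > 0, psv / pv, 0))
  res <- tibble::tibble(group = rownames(pg),
                        population_share = as.numeric(pg) / sum(pop),
                        ch = ch, di = di, ecvi = ch * di)
  res$contribution <- if (total[["ecvi"]] > 0) {
    res$population_share * res$ecvi / total[["ecvi"]]
  } else NA_real_
  res
}

#' Indicator and dimension decomposition of the ECVI
#'
#' `CH_i` is the population-weighted share of regions that are vulnerable
#' (`c >= k_p`) and deprived in indicator i; the pooled index satisfies
#' `ECVI = sum_i w_i CH_i` exactly, and each indicator contributes
#' `w_i CH_i / ECVI`. Dimension rows sum their member indicators.
#'
#' @inheritParams compute_ecvi
#' @param dep long deprivation matrix (flags are required here).
#' @return list with tibbles `indicator` (`indicator_id`, `dimension`,
#'   `weight`, `ch_indicator`, `contribution`) and `dimension`
#'   (`dimension`, `contribution`); contributions are `NA` when ECVI = 0.
#' @export
decompose_by_indicator <- function(dep, populations, k_p = 0.25,
                                   schema = attr(dep, "schema"),
                                   weighted = TRUE) {
  .check_schema(schema)
  if (!"deprived" %in% names(dep)) {
    stop("indicator decomposition needs the per-indicator flags")
  }
  scores <- weighted_score(dep, schema)
  pop <- .match_populations(populations, scores$region_id, weighted)
  vul <- stats::setNames(scores$score >= k_p, scores$region_id)
  popn <- stats::setNames(pop, scores$region_id)
  rid <- as.character(dep$region_id)
  num <- rowsum(popn[rid] * dep$deprived * vul[rid],
                as.character(dep$indicator_id))
  ch_i <- stats::setNames(as.numeric(num) / sum(pop), rownames(num))
  ind <- schema[c("indicator_id", "dimension", "weight")]
  ind$ch_indicator <- as.numeric(ch_i[ind$indicator_id])
  ecvi <- sum(ind$weight * ind$ch_indicator)
  ind$contribution <- if (ecvi > 0) ind$weight * ind$ch_indicator / ecvi
                      else NA_real_
  dim_contr <- rowsum(ind$contribution, ind$dimension)
  dim_tab <- tibble::tibble(dimension = rownames(dim_contr),
                            contribution = as.numeric(dim_contr))
  list(indicator = ind, dimension = dim_tab, ecvi = ecvi)
}

#' Standard errors for CH, DI and the ECVI
#'
#' Default is a nonparametric bootstrap over regions: resample regions with
#' replacement (keeping their scores and populations), recompute CH/DI/ECVI,
#' and take the SD over `B` replicates. The `linearization` option treats
#' ECVI and CH as population-weighted means of (censored) region scores and
#' uses the standard ratio-estimator linearization, with a delta-method SE
#' for DI = ECVI / CH.
#'
#' @param dep scores tibble or long deprivation matrix.
#' @param populations as in [compute_ecvi()].
#' @param k_p multidimensional cutoff.
#' @param method `"bootstrap"` or `"linearization"`.
#' @param B bootstrap replicates (default 1000; fewer than 50 warns).
#' @param seed bootstrap seed.
#' @param schema schema when `dep` carries raw flags.
#' @return tibble `ch_se`, `di_se`, `ecvi_se`.
#' @export
estimate_se <- function(dep, populations, k_p = 0.25,
                        method = c("bootstrap", "linearization"),
                        B = 1000L, seed = 1L, schema = NULL) {
  method <- match.arg(method)
  scores <- .as_scores(dep, schema)
  n <- nrow(scores)
  if (n < 2L) stop("need at least 2 regions to estimate a standard error")
  pop <- .match_populations(populations, scores$region_id)
  s <- scores$score
  if (method == "bootstrap") {
    if (B < 50L) warning("B < 50 bootstrap replicates is unreliable",
                         call. = FALSE)
    reps <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
      t(apply(idx, 1L, function(i) .ecvi_point(s[i], pop[i], k_p)[1:3]))
    })
    tibble::tibble(ch_se = stats::sd(reps[, "ch"]),
                   di_se = stats::sd(reps[, "di"]),
                   ecvi_se = stats::sd(reps[, "ecvi"]))
  } else {
    est <- .ecvi_point(s, pop, k_p)
    w <- pop / mean(pop)
    vul <- as.numeric(s >= k_p)
    # linearized values of the two weighted-mean ratios
    u_ch <- w * (vul - est["ch"]) / n
    u_ecvi <- w * (s * vul - est["ecvi"]) / n
    v_ch <- n / (n - 1) * sum((u_ch - mean(u_ch))^2)
    v_ecvi <- n / (n - 1) * sum((u_ecvi - mean(u_ecvi))^2)
    cov_ce <- n / (n - 1) * sum((u_ch - mean(u_ch)) * (u_ecvi - mean(u_ecvi)))
    di_se <- if (est["ch"] > 0 && est["ecvi"] > 0) {
      est["di"] * sqrt(max(0, v_ecvi / est["ecvi"]^2 + v_ch / est["ch"]^2 -
                              2 * cov_ce / (est["ecvi"] * est["ch"])))
    } else 0
    tibble::tibble(ch_se = sqrt(v_ch), di_se = as.numeric(di_se),
                   ecvi_se = sqrt(v_ecvi))
  }
}
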