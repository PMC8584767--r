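#' Choosing the multidimensional cutoff k_p
#'
#' Sensitivity curves trace ECVI, CH and DI over a grid of candidate
#' cutoffs; the forward-local-variance criterion picks the grid point whose
#' next-`t` window of curve values has minimal (population) variance — the
#' start of the flattest forward stretch; dominance checks whether one
#' group's curve sits weakly above another's over the whole feasible grid.
#' The criterion is advisory: reports always carry the vulnerable share at
#' each candidate so an over-censoring optimum (too few vulnerable regions)
#' is visible, alongside the CH/DI intersection point.
#'
#' @name kp_selection
NULL

#' Sensitivity curve of an AF statistic over a k_p grid
#'
#' @inheritParams compute_ecvi
#' @param statistic one of `"ecvi"`, `"ch"`, `"di"`.
#' @param grid strictly increasing cutoffs in `(0, 1]` (default 0.05 to 1
#'   by 0.05).
#' @param group optional label attached to the curve.
#' @return tibble `k_p`, `value`, `statistic`, `group`,
#'   `vulnerable_share`.
#' @export
sensitivity_curve <- function(dep, populations,
                              statistic = c("ecvi", "ch", "di"),
                              grid = seq(0.05, 1, by = 0.05),
                              schema = NULL, weighted = TRUE,
                              group = "overall") {
  statistic <- match.arg(statistic)
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1)) {
    stop("grid must be strictly increasing within (0, 1]")
  }
  scores <- .as_scores(dep, schema)
  pop <- .match_populations(populations, scores$region_id, weighted)
  vals <- vapply(grid, function(k) {
    est <- .ecvi_point(scores$score, pop, k)
    c(est[[statistic]], est[["vul_share"]])
  }, numeric(2))
  tibble::tibble(k_p = grid, value = vals[1L, ], statistic = statistic,
                 group = group, vulnerable_share = vals[2L, ])
}

# population variance (divide by length) of forward windows of length t;
# returns NA for starts whose window runs off the grid
.window_variances <- function(values, t) {
  n <- length(values)
  vapply(seq_len(n), function(p) {
    if (p + t - 1L > n) return(NA_real_)
    w <- values[p:(p + t - 1L)]
    mean((w - mean(w))^2)
  }, numeric(1))
}

#' Forward-local-variance optimum on a sensitivity curve
#'
#' For each grid index p with a full forward window, computes the population
#' variance of the `t` curve values starting at p and returns the k_p with
#' minimal window variance; ties resolve to the smallest k_p.
#'
#' @param curve tibble from [sensitivity_curve()] (columns `k_p`, `value`).
#' @param t forward window length (default 3, >= 2).
#' @return list with `k_p_opt`, `window_variance` and the per-start
#'   `windows` tibble.
#' @export
forward_local_variance_optimum <- function(curve, t = 3L) {
  stopifnot(t >= 2L)
  if (nrow(curve) <= t) stop("grid must be longer than the window length")
  v <- .window_variances(curve$value, t)
  if (all(is.na(v))) stop("degenerate grid: no full forward window")
  best <- which.min(v) # which.min takes the first minimum: smallest k_p
  list(k_p_opt = curve$k_p[best], window_variance = v[best],
       windows = tibble::tibble(k_p = curve$k_p, window_variance = v))
}

#' Forward-local-variance optimum averaged across group curves
#'
#' Per grid index, averages the forward window variance across the group
#' curves (which must share a grid) and returns the argmin; ties resolve to
#' the smallest k_p.
#'
#' @param curves tibble with columns `k_p`, `value`, `group` (stacked
#'   [sensitivity_curve()] outputs), or a list of curves.
#' @inheritParams forward_local_variance_optimum
#' @return list with `k_p_opt`, `mean_window_variance` and `windows`.
#' @export
grouped_optimum <- function(curves, t = 3L) {
  stopifnot(t >= 2L)
  if (is.data.frame(curves)) {
    curves <- split(curves, curves$group)
  }
  grid <- curves[[1L]]$k_p
  for (cu in curves) {
    if (!isTRUE(all.equal(cu$k_p, grid))) stop("curves must share a grid")
  }
  if (length(grid) <= t) stop("grid must be longer than the window length")
  V <- vapply(curves, function(cu) .window_variances(cu$value, t),
              numeric(length(grid)))
  mv <- rowMeans(V)
  if (all(is.na(mv))) stop("degenerate grid: no full forward window")
  best <- which.min(mv)
  list(k_p_opt = grid[best], mean_window_variance = mv[best],
       windows = tibble::tibble(k_p = grid, mean_window_variance = mv))
}

#' Pairwise weak-dominance report between group curves
#'
#' For each ordered pair of groups, reports whether curve A >= curve B at
#' every grid point where either curve is positive (weak dominance), and
#' lists the violating grid points otherwise.
#'
#' @param curves stacked curves tibble (`k_p`, `value`, `group`).
#' @param tol numeric slack treated as equality (default 1e-12).
#' @return tibble `group_a`, `group_b`, `dominates`, `violations`
#'   (list-column of violating k_p).
#' @export
dominance_check <- function(curves, tol = 1e-12) {
  groups <- unique(curves$group)
  grid <- sort(unique(curves$k_p))
  get <- function(g) {
    cu <- curves[curves$group == g, ]
    cu$value[match(grid, cu$k_p)]
  }
  out <- list()
  for (a in groups) for (b in setdiff(groups, a)) {
    va <- get(a); vb <- get(b)
    active <- va > tol | vb > tol
    viol <- grid[active & (va < vb - tol)]
    out[[length(out) + 1L]] <- tibble::tibble(
      group_a = a, group_b = b, dominates = length(viol) == 0L,
      violations = list(viol)
    )
  }
  dplyr::bind_rows(out)
}

#' CH/DI intersection point
#'
#' The grid point where the censored headcount and deprivation intensity
#' curves are closest (minimal |CH - DI|), the secondary advisory used to
#' justify a lower cutoff than the variance criterion when the latter
#' over-censors.
#'
#' @inheritParams sensitivity_curve
#' @return list with `k_p`, `ch`, `di`.
#' @export
ch_di_intersection <- function(dep, populations,
                               grid = seq(0.05, 1, by = 0.05),
                               schema = NULL, weighted = TRUE) {
  ch <- sensitivity_curve(dep, populations, "ch", grid, schema, weighted)
  di <- sensitivity_curve(dep, populations, "di", grid, schema, weighted)
  gap <- abs(ch$value - di$value)
  best <- which.min(gap)
  list(k_p = grid[best], ch = ch$value[best], di = di$value[best])
}

#' Full cutoff-selection report
#'
#' Bundles the per-group sensitivity curves, the single-curve and
#' group-averaged forward-local-variance optima, the CH/DI intersection,
#' the user-chosen cutoff and the vulnerable share at each candidate.
#'
#' @inheritParams sensitivity_curve
#' @param partition optional tibble `region_id`, `group` for group curves.
#' @param t forward window length.
#' @param chosen_kp the analyst's cutoff to record alongside the advisories
#'   (default 0.25).
#' @return list (JSON-serializable) with `curves`, `criterion_optimum`,
#'   `grouped_optimum`, `intersection_point`, `chosen_kp`,
#'   `vulnerable_share` and `dominance`.
#' @export
kp_report <- function(dep, populations, partition = NULL,
                      grid = seq(0.05, 1, by = 0.05), t = 3L,
                      chosen_kp = 0.25, schema = NULL, weighted = TRUE) {
  scores <- .as_scores(dep, schema)
  overall <- sensitivity_curve(scores, populations, "ecvi", grid,
                               weighted = weighted)
  opt <- forward_local_variance_optimum(overall, t)
  curves <- overall
  gopt <- NULL
  dom <- NULL
  if (!is.null(partition)) {
    grp <- lapply(unique(partition$group), function(g) {
      ids <- partition$region_id[partition$group == g]
      sensitivity_curve(scores[scores$region_id %in% ids, ], populations,
                        "ecvi", grid, weighted = weighted, group = g)
    })
    curves <- dplyr::bind_rows(c(list(overall), grp))
    gopt <- grouped_optimum(dplyr::bind_rows(grp), t)
    dom <- dominance_check(dplyr::bind_rows(grp))
  }
  share_at <- function(k) {
    pop <- .match_populations(populations, scores$region_id, weighted)
    .ecvi_point(scores$score, pop, k)[["vul_share"]]
  }
  list(
    curves = curves,
    criterion_optimum = list(k_p = opt$k_p_opt,
                             vulnerable_share = share_at(opt$k_p_opt)),
    grouped_optimum = if (is.null(gopt)) NULL else
      list(k_p = gopt$k_p_opt, vulnerable_share = share_at(gopt$k_p_opt)),
    intersection_point = ch_di_intersection(scores, populations, grid,
                                            weighted = weighted),
    chosen_kp = list(k_p = chosen_kp, vulnerable_share = share_at(chosen_kp)),
    dominance = dom,
    t = t
  )
}
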