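#' Extreme climate indices from daily weather series
#'
#' Functions in this file compute the seven ETCCDI/Climdex-style indices used
#' as exposure indicators — TXx, TNx, TX90p, TN90p, DTR, CDD and R99p — from
#' long-format daily series, and code them into cross-region quintile
#' categories for the mixed-membership (Grade of Membership) stage.
#'
#' A daily series is a data frame with columns `region_id`, `date` (Date),
#' `tmax`, `tmin` (degrees C) and `precip` (mm/day). Missing values are `NA`,
#' never silently zero. One scalar per region per index summarizes the whole
#' multi-year record: TXx/TNx as the mean of annual maxima, CDD and R99p as
#' the mean of annual values, TX90p/TN90p as a percentage over all days of
#' the record, and DTR as the mean of monthly means.
#'
#' @name climate_indices
NULL

#' Validate a daily climate series
#'
#' Checks the structural invariants of a daily series: required columns,
#' strictly increasing dates within region, `tmax >= tmin` whenever both are
#' present, and nonnegative precipitation.
#'
#' @param series data frame with columns `region_id`, `date`, `tmax`, `tmin`,
#'   `precip`.
#' @return `series`, invisibly, with `date` coerced to `Date`.
#' @export
validate_daily_series <- function(series) {
  req <- c("region_id", "date", "tmax", "tmin", "precip")
  miss <- setdiff(req, names(series))
  if (length(miss) > 0L) {
    stop("daily series is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(series) == 0L) stop("daily series is empty")
  series$date <- as.Date(series$date)
  bad_order <- series |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(ok = all(diff(as.numeric(.data$date)) > 0),
                     .groups = "drop")
  if (!all(bad_order$ok)) {
    stop("dates must be strictly increasing within region: ",
         paste(bad_order$region_id[!bad_order$ok], collapse = ", "))
  }
  both <- !is.na(series$tmax) & !is.na(series$tmin)
  if (any(series$tmax[both] < series$tmin[both])) {
    stop("tmax < tmin found in daily series")
  }
  if (any(series$precip < 0, na.rm = TRUE)) {
    stop("negative precipitation found in daily series")
  }
  invisible(series)
}

.year <- function(d) as.integer(format(d, "%Y"))
.month_key <- function(d) format(d, "%Y-%m")
# day-of-year on a leap calendar so Feb 29 keeps its own slot
.doy366 <- function(d) {
  as.integer(as.Date(paste0("2000-", format(d, "%m-%d")))) -
    as.integer(as.Date("2000-01-01")) + 1L
}

# Drop blocks (years or months) whose share of missing values for `var`
# exceeds `missing_tolerance`; warn when anything is dropped.
.complete_blocks <- function(df, block_key, var, missing_tolerance, what) {
  keep <- tapply(is.na(df[[var]]), block_key, mean) <= missing_tolerance
  dropped <- names(keep)[!keep]
  if (length(dropped) > 0L) {
    warning(sprintf("%s: skipping %d block(s) with > %.0f%% missing %s (%s)",
                    what, length(dropped), 100 * missing_tolerance, var,
                    paste(utils::head(dropped, 5L), collapse = ", ")),
            call. = FALSE)
  }
  df[keep[as.character(block_key)], , drop = FALSE]
}

#' Mean of within-block maxima of a temperature variable (TXx / TNx)
#'
#' For each region, takes the maximum of `variable` within each block (year
#' or month) and returns the mean over blocks, the multi-year summary of the
#' Climdex block-maximum indices TXx (tmax) and TNx (tmin).
#'
#' @param series daily climate series (see [validate_daily_series()]).
#' @param variable `"tmax"` or `"tmin"`.
#' @param block `"year"` or `"month"` blocks.
#' @param missing_tolerance maximum tolerated share of missing days in a
#'   block before the block is skipped (default 0.2).
#' @return tibble with columns `region_id`, `value` (degrees C).
#' @export
block_maximum_index <- function(series, variable = c("tmax", "tmin"),
                                block = c("year", "month"),
                                missing_tolerance = 0.2) {
  variable <- match.arg(variable)
  block <- match.arg(block)
  series <- validate_daily_series(series)
  per_region <- function(df) {
    key <- if (block == "year") .year(df$date) else .month_key(df$date)
    df <- .complete_blocks(df, key, variable, missing_tolerance,
                           paste0("block_maximum_index[", df$region_id[1L], "]"))
    if (nrow(df) == 0L) return(NA_real_)
    key <- if (block == "year") .year(df$date) else .month_key(df$date)
    mean(tapply(df[[variable]], key, max, na.rm = TRUE))
  }
  series |>
    dplyr::group_by(.data$region_id) |>
    dplyr::group_modify(~ tibble::tibble(value = per_region(.x |>
      dplyr::mutate(region_id = .y$region_id)))) |>
    dplyr::ungroup()
}

# Calendar-day percentile thresholds: for each day-of-year, the q-th
# percentile of values falling in a centered `window`-day window across all
# base-period years.
.calendar_thresholds <- function(dates, values, q, window) {
  doy <- .doy366(dates)
  half <- (window - 1L) %/% 2L
  thr <- rep(NA_real_, 366L)
  for (d in sort(unique(doy))) {
    dist <- abs(doy - d)
    dist <- pmin(dist, 366L - dist) # circular
    v <- values[dist <= half]
    v <- v[!is.na(v)]
    if (length(v) > 0L) thr[d] <- ecvi_quantile(v, q / 100)
  }
  thr
}

#' Percentage of days exceeding a calendar-day percentile (TX90p / TN90p)
#'
#' For each calendar day the threshold is the `q`-th percentile of the
#' variable in a centered `window`-day window across all base-period years.
#' Returns, per region, 100 times the share of non-missing days whose value
#' strictly exceeds their calendar-day threshold.
#'
#' @inheritParams block_maximum_index
#' @param q percentile (default 90).
#' @param base_period length-2 Date vector delimiting the threshold base
#'   period; defaults to the full series range. Must span at least one year.
#' @param window centered window width in days (default 5).
#' @return tibble with columns `region_id`, `value` (% of days in `[0, 100]`).
#' @export
exceedance_percentage <- function(series, variable = c("tmax", "tmin"),
                                  q = 90, base_period = NULL, window = 5L) {
  variable <- match.arg(variable)
  series <- validate_daily_series(series)
  if (is.null(base_period)) base_period <- range(series$date)
  base_period <- as.Date(base_period)
  if (as.numeric(diff(base_period)) < 364) {
    stop("base period must span at least one full year")
  }
  per_region <- function(df) {
    inb <- df$date >= base_period[1L] & df$date <= base_period[2L]
    if (!any(inb)) stop("base period not contained in series for region ",
                        df$region_id[1L])
    thr <- .calendar_thresholds(df$date[inb], df[[variable]][inb], q, window)
    v <- df[[variable]]
    ok <- !is.na(v)
    t_day <- thr[.doy366(df$date)]
    exceed <- ok & !is.na(t_day) & v > t_day
    100 * sum(exceed) / sum(ok)
  }
  series |>
    dplyr::group_by(.data$region_id) |>
    dplyr::group_modify(~ tibble::tibble(value = per_region(.x |>
      dplyr::mutate(region_id = .y$region_id)))) |>
    dplyr::ungroup()
}

#' Mean diurnal temperature range (DTR)
#'
#' Mean over months of the monthly mean of `tmax - tmin` over days where both
#' are present. Months with no paired days, or with more than
#' `missing_tolerance` of pairs missing, are skipped with a warning.
#'
#' @inheritParams block_maximum_index
#' @return tibble with columns `region_id`, `value` (degrees C).
#' @export
daily_temperature_range <- function(series, missing_tolerance = 0.2) {
  series <- validate_daily_series(series)
  per_region <- function(df) {
    df$dtr <- ifelse(!is.na(df$tmax) & !is.na(df$tmin),
                     df$tmax - df$tmin, NA_real_)
    key <- .month_key(df$date)
    df <- .complete_blocks(df, key, "dtr", missing_tolerance,
                           paste0("daily_temperature_range[", df$region_id[1L], "]"))
    if (nrow(df) == 0L) return(NA_real_)
    mean(tapply(df$dtr, .month_key(df$date), mean, na.rm = TRUE))
  }
  series |>
    dplyr::group_by(.data$region_id) |>
    dplyr::group_modify(~ tibble::tibble(value = per_region(.x |>
      dplyr::mutate(region_id = .y$region_id)))) |>
    dplyr::ungroup()
}

# longest run of TRUE in a logical vector; NA breaks a run
.longest_run <- function(x) {
  x[is.na(x)] <- FALSE
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Longest annual dry spell (CDD)
#'
#' Per calendar year, the maximum run of consecutive days with precipitation
#' below `wet_threshold` (Climdex CDD); returns the mean of annual maxima per
#' region. Missing precipitation days interrupt a dry run rather than
#' extending it.
#'
#' @inheritParams block_maximum_index
#' @param wet_threshold wet-day threshold in mm (default 1).
#' @return tibble with columns `region_id`, `value` (days).
#' @export
longest_dry_spell <- function(series, wet_threshold = 1.0,
                              missing_tolerance = 0.2) {
  series <- validate_daily_series(series)
  per_region <- function(df) {
    key <- .year(df$date)
    df <- .complete_blocks(df, key, "precip", missing_tolerance,
                           paste0("longest_dry_spell[", df$region_id[1L], "]"))
    if (nrow(df) == 0L) return(NA_real_)
    dry <- df$precip < wet_threshold
    mean(tapply(seq_len(nrow(df)), .year(df$date),
                function(idx) .longest_run(dry[idx])))
  }
  series |>
    dplyr::group_by(.data$region_id) |>
    dplyr::group_modify(~ tibble::tibble(value = per_region(.x |>
      dplyr::mutate(region_id = .y$region_id)))) |>
    dplyr::ungroup()
}

#' Mean annual precipitation total above the wet-day percentile (R99p)
#'
#' The threshold is the `q`-th percentile of base-period wet-day
#' (`>= wet_threshold` mm) precipitation; the index is the mean over years of
#' the annual sum of precipitation on days strictly above that threshold.
#'
#' @inheritParams exceedance_percentage
#' @param q percentile of wet-day amounts (default 99).
#' @param wet_threshold wet-day definition in mm (default 1, the Climdex
#'   convention).
#' @return tibble with columns `region_id`, `value` (mm).
#' @export
extreme_wet_total <- function(series, q = 99, base_period = NULL,
                              wet_threshold = 1.0) {
  series <- validate_daily_series(series)
  if (is.null(base_period)) base_period <- range(series$date)
  base_period <- as.Date(base_period)
  per_region <- function(df) {
    inb <- df$date >= base_period[1L] & df$date <= base_period[2L]
    wet <- df$precip[inb]
    wet <- wet[!is.na(wet) & wet >= wet_threshold]
    if (length(wet) == 0L) {
      stop("no wet day (precip >= ", wet_threshold, " mm) in base period ",
           "for region ", df$region_id[1L])
    }
    thr <- ecvi_quantile(wet, q / 100)
    extreme <- !is.na(df$precip) & df$precip > thr
    annual <- tapply(ifelse(extreme, df$precip, 0), .year(df$date), sum)
    mean(annual)
  }
  series |>
    dplyr::group_by(.data$region_id) |>
    dplyr::group_modify(~ tibble::tibble(value = per_region(.x |>
      dplyr::mutate(region_id = .y$region_id)))) |>
    dplyr::ungroup()
}

#' Compute the full extreme-index table
#'
#' Convenience wrapper computing all seven indices per region: `txx`, `tnx`,
#' `tx90p`, `tn90p`, `dtr`, `cdd`, `r99p`.
#'
#' @inheritParams exceedance_percentage
#' @param wet_threshold wet-day threshold in mm.
#' @param missing_tolerance maximum tolerated missing share per block.
#' @return tibble with one row per region and one column per index.
#' @export
compute_climate_indices <- function(series, base_period = NULL,
                                    wet_threshold = 1.0, window = 5L,
                                    missing_tolerance = 0.2) {
  series <- validate_daily_series(series)
  out <- list(
    txx   = block_maximum_index(series, "tmax", "year", missing_tolerance),
    tnx   = block_maximum_index(series, "tmin", "year", missing_tolerance),
    tx90p = exceedance_percentage(series, "tmax", 90, base_period, window),
    tn90p = exceedance_percentage(series, "tmin", 90, base_period, window),
    dtr   = daily_temperature_range(series, missing_tolerance),
    cdd   = longest_dry_spell(series, wet_threshold, missing_tolerance),
    r99p  = extreme_wet_total(series, 99, base_period, wet_threshold)
  )
  tab <- out$txx["region_id"]
  for (nm in names(out)) tab[[nm]] <- out[[nm]]$value[
    match(tab$region_id, out[[nm]]$region_id)]
  tibble::as_tibble(tab)
}

#' Code an index table into cross-region quintile categories
#'
#' Per item, regions are assigned to categories `1..n_categories` by empirical
#' quantile of the cross-region distribution. Assignment is rank-based with a
#' stable tie-break on `region_id`, so it is invariant under strictly
#' monotone transforms of an item's values. If every region shares the same
#' value the item is degenerate: all regions get category 1 and a warning is
#' emitted; partial heavy ties warn but keep the stable rank assignment.
#'
#' @param index_table wide tibble with `region_id` and one numeric column per
#'   item (e.g. the output of [compute_climate_indices()]).
#' @param n_categories number of categories (default 5 quintiles).
#' @return long tibble `region_id`, `item_id`, `category` with exactly one
#'   row per (region, item).
#' @export
categorize_quantiles <- function(index_table, n_categories = 5L) {
  items <- setdiff(names(index_table), "region_id")
  if (nrow(index_table) < n_categories) {
    warning("fewer regions than categories; some categories will be empty",
            call. = FALSE)
  }
  out <- lapply(items, function(it) {
    v <- index_table[[it]]
    if (anyNA(v)) stop("missing index value for item ", it)
    if (length(unique(v)) == 1L) {
      warning("item ", it, " is constant across regions; all assigned ",
              "category 1", call. = FALSE)
      cat_v <- rep(1L, length(v))
    } else {
      if (anyDuplicated(v)) {
        warning("ties in item ", it,
                "; categories assigned by rank with stable region_id ",
                "tie-break", call. = FALSE)
      }
      cat_v <- rank_ntile(v, n_categories, tie_key = index_table$region_id)
    }
    tibble::tibble(region_id = index_table$region_id, item_id = it,
                   category = cat_v)
  })
  dplyr::bind_rows(out)
}

#' Read / write the standard CSV formats
#'
#' `read_daily_series()` reads a long-format CSV with columns
#' `region_id,date,tmax,tmin,precip` (ISO-8601 dates, empty fields for
#' missing); `write_index_table()` and `write_category_matrix()` write the
#' index table and the categorical matrix.
#'
#' @param path file path.
#' @return `read_daily_series()` returns a validated tibble.
#' @export
read_daily_series <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    region_id = readr::col_character(),
    date = readr::col_date(),
    tmax = readr::col_double(),
    tmin = readr::col_double(),
    precip = readr::col_double()
  ))
  validate_daily_series(df)
  df
}

#' @rdname read_daily_series
#' @param index_table,categories objects to serialize.
#' @export
write_index_table <- function(index_table, path) {
  readr::write_csv(index_table, path)
  invisible(path)
}

#' @rdname read_daily_series
#' @export
write_category_matrix <- function(categories, path) {
  readr::write_csv(categories, path)
  invisible(path)
}
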