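#' Compute specific daily growth rate from cell counts
#'
#' Batch-culture growth rate over one assay cycle,
#' \eqn{\mu = (\ln N_d - \ln N_0)/d}: the exponential rate implied by the
#' cell abundance at inoculation (`n0`), the abundance at the end of the
#' cycle (`nd`) and the cycle length in days (`duration`).
#'
#' @param n0 Cell abundance at the start of the batch cycle (cells). Must be
#'   positive.
#' @param nd Cell abundance at the end of the cycle (cells). Must be positive.
#' @param duration Length of the cycle in days. Must be positive.
#' @return Specific growth rate per day (numeric, vectorized over inputs).
#' @examples
#' compute_growth_rate(1e5, 1e5 * exp(2), 2) # exactly 1 per day
#' compute_growth_rate(1e5, 8e5, 5)          # log(8)/5
#' @export
compute_growth_rate <- function(n0, nd, duration) {
  if (!is.numeric(n0) || !is.numeric(nd) || !is.numeric(duration)) {
    abort("`n0`, `nd` and `duration` must be numeric.",
          class = "thermnorm_invalid_input")
  }
  bad <- !is.finite(n0) | !is.finite(nd) | !is.finite(duration) |
    n0 <= 0 | nd <= 0 | duration <= 0
  if (any(bad)) {
    abort(
      sprintf("cell counts and duration must be positive and finite (first offending element: %d)",
              which(bad)[1]),
      class = "thermnorm_invalid_input"
    )
  }
  (log(nd) - log(n0)) / duration
}

assay_required_cols <- c("replicate_id", "selection_temp", "pco2", "assay_temp")
assay_count_cols <- c("n0", "nd", "duration")

#' Validate (and complete) a growth-assay table
#'
#' Coerces a data frame to the tidy assay format used throughout the package:
#' one row per (replicate population, assay temperature) with treatment
#' labels, a growth rate, and a logical `censored` flag. Growth rates missing
#' from rows that carry cell counts are filled in with
#' [compute_growth_rate()]; rates present alongside counts are checked for
#' consistency.
#'
#' @param x A data frame with columns `replicate_id`, `selection_temp`,
#'   `pco2`, `assay_temp` and either `growth_rate` or all of
#'   `n0`, `nd`, `duration`.
#' @param rate_tol Absolute tolerance when cross-checking a recorded
#'   `growth_rate` against the one implied by cell counts.
#' @return A tibble with at least the columns above plus `growth_rate` and
#'   `censored`, ordered by replicate and assay temperature.
#' @export
as_assay_data <- function(x, rate_tol = 1e-6) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame.", class = "thermnorm_parse_error")
  }
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(assay_required_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "thermnorm_parse_error")
  }
  has_counts <- all(assay_count_cols %in% names(x))
  if (!("growth_rate" %in% names(x)) && !has_counts) {
    abort("need either a `growth_rate` column or all of `n0`, `nd`, `duration`.",
          class = "thermnorm_parse_error")
  }
  num_cols <- intersect(c("selection_temp", "pco2", "assay_temp",
                          "growth_rate", assay_count_cols), names(x))
  for (cl in num_cols) {
    v <- x[[cl]]
    if (is.integer(v)) x[[cl]] <- as.double(v)
    if (is.character(v) || is.factor(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric value in column `%s` at row %d: \"%s\"",
                      cl, bad[1], as.character(v)[bad[1]]),
              class = "thermnorm_parse_error")
      }
      x[[cl]] <- vn
    }
  }
  if (!("growth_rate" %in% names(x))) x$growth_rate <- NA_real_
  x$replicate_id <- as.character(x$replicate_id)

  if (has_counts) {
    fill <- is.na(x$growth_rate) & !is.na(x$n0) & !is.na(x$nd) & !is.na(x$duration)
    if (any(fill)) {
      x$growth_rate[fill] <- compute_growth_rate(
        x$n0[fill], x$nd[fill], x$duration[fill])
    }
    check <- !is.na(x$growth_rate) & !is.na(x$n0) & !is.na(x$nd) & !is.na(x$duration)
    if (any(check)) {
      implied <- compute_growth_rate(x$n0[check], x$nd[check], x$duration[check])
      off <- which(abs(implied - x$growth_rate[check]) > rate_tol)
      if (length(off) > 0) {
        abort(sprintf(
          "row %d: recorded growth_rate %.6g disagrees with (ln nd - ln n0)/duration = %.6g",
          which(check)[off[1]], x$growth_rate[check][off[1]], implied[off[1]]),
          class = "thermnorm_parse_error")
      }
    }
  }
  if (any(is.na(x$growth_rate))) {
    abort(sprintf("row %d has neither a growth rate nor complete cell counts",
                  which(is.na(x$growth_rate))[1]),
          class = "thermnorm_parse_error")
  }
  if (any(!is.finite(x$assay_temp))) {
    abort("`assay_temp` must be finite for every record.",
          class = "thermnorm_parse_error")
  }
  if (any(x$growth_rate < 0)) {
    # negative rates are not measurable in these assays; zero stands in for them
    abort(sprintf("row %d has a negative growth rate; record 0 for no growth",
                  which(x$growth_rate < 0)[1]),
          class = "thermnorm_parse_error")
  }
  dup <- duplicated(x[, c("replicate_id", "assay_temp")])
  if (any(dup)) {
    d <- x[which(dup)[1], ]
    abort(sprintf("duplicate record for replicate \"%s\" at %g °C",
                  d$replicate_id, d$assay_temp),
          class = "thermnorm_parse_error")
  }
  one_label <- vapply(split(x, x$replicate_id), function(u) {
    length(unique(u$selection_temp)) == 1 && length(unique(u$pco2)) == 1
  }, logical(1))
  if (!all(one_label)) {
    abort(sprintf("replicate \"%s\" carries more than one treatment label",
                  names(one_label)[!one_label][1]),
          class = "thermnorm_parse_error")
  }
  if (!("censored" %in% names(x))) x$censored <- FALSE
  x$censored <- as.logical(x$censored)
  x$censored[is.na(x$censored)] <- FALSE
  x <- dplyr::arrange(x, .data$replicate_id, .data$assay_temp)
  keep <- c(assay_required_cols, "growth_rate",
            intersect(assay_count_cols, names(x)), "censored")
  x[, keep]
}

#' Read a growth-assay table from delimited text
#'
#' Reads a CSV or TSV file (chosen from the extension, or forced with
#' `delim`) and validates it with [as_assay_data()]. Rows that carry cell
#' counts (`n0`, `nd`, `duration`) but no `growth_rate` get their rate
#' computed. `col_map` renames nonstandard headers — e.g. those of a
#' repository export — onto the package schema before validation.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; default `","` for `.csv`, `"\t"` otherwise.
#' @param col_map Optional named character vector `c(standard = "file_column")`
#'   mapping schema names to the file's column names.
#' @inheritParams as_assay_data
#' @return A validated assay tibble (see [as_assay_data()]).
#' @export
read_assay_table <- function(path, delim = NULL, col_map = NULL, rate_tol = 1e-6) {
  if (!file.exists(path)) {
    abort(sprintf("input file does not exist: %s", path),
          class = "thermnorm_parse_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  # base parser: correctly rounded string-to-double conversion, so tables
  # written by write_assay_table() round-trip bit for bit
  x <- utils::read.delim(path, sep = delim, header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(x)) {
        names(x)[names(x) == col_map[[std]]] <- std
      }
    }
  }
  as_assay_data(x, rate_tol = rate_tol)
}

#' Write a growth-assay table to delimited text
#'
#' Writes the tibble with full double precision so that
#' `read_assay_table(write_assay_table(x, f))` round-trips every numeric
#' field exactly.
#'
#' @param x A validated assay tibble.
#' @param path Output path; `.csv` gives comma-separated output, anything
#'   else tab-separated.
#' @param drop_censored If `TRUE`, censored records are omitted from the
#'   file (the default keeps them, with their flag, so nothing is lost).
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(x, path, drop_censored = FALSE) {
  x <- as_assay_data(x)
  if (drop_censored) x <- x[!x$censored, ]
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # 17 significant digits guarantee an exact double round trip
  for (cl in names(x)) {
    if (is.double(x[[cl]])) x[[cl]] <- sprintf("%.17g", x[[cl]])
  }
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}

#' Censor the 27 degree record of replicates that stopped growing
#'
#' Growth assays cannot measure negative rates, so a recorded 0 near the
#' upper thermal limit usually overestimates the true rate. Whenever a
#' replicate shows no growth (rate at or below zero) at 26 or 27 degrees C,
#' the 27 degree record is flagged `censored` and excluded from curve
#' fitting downstream. Records are never dropped from the table, only
#' flagged, and every flag set is listed in the `censor_log` attribute.
#'
#' @param x A validated assay tibble.
#' @param mode `"or"` (default) removes the 27 degree record when growth is
#'   absent at *either* 26 or 27 degrees; `"and"` only when absent at both.
#' @param temp_tol Records within `temp_tol` degrees C of 26/27 count as the
#'   26/27 degree measurements (assay setpoints are not exact).
#' @return The assay tibble with updated `censored` flags and an attribute
#'   `censor_log`: a tibble with one row per newly censored record.
#' @export
censor_no_growth <- function(x, mode = c("or", "and"), temp_tol = 0.5) {
  mode <- match.arg(mode)
  x <- as_assay_data(x)
  log_rows <- list()
  for (id in unique(x$replicate_id)) {
    idx <- which(x$replicate_id == id)
    u <- x[idx, ]
    i26 <- idx[abs(u$assay_temp - 26) <= temp_tol]
    i27 <- idx[abs(u$assay_temp - 27) <= temp_tol]
    if (length(i26) == 0 || length(i27) == 0) next  # rule vacuous
    no26 <- any(x$growth_rate[i26] <= 0)
    no27 <- any(x$growth_rate[i27] <= 0)
    hit <- if (mode == "or") no26 || no27 else no26 && no27
    if (hit && any(!x$censored[i27])) {
      newly <- i27[!x$censored[i27]]
      x$censored[newly] <- TRUE
      log_rows[[length(log_rows) + 1]] <- tibble::tibble(
        replicate_id = id,
        assay_temp = x$assay_temp[newly],
        growth_rate = x$growth_rate[newly],
        reason = sprintf("no growth at 26/27 °C (mode \"%s\")", mode)
      )
    }
  }
  attr(x, "censor_log") <- if (length(log_rows) > 0) {
    dplyr::bind_rows(log_rows)
  } else {
    tibble::tibble(replicate_id = character(), assay_temp = numeric(),
                   growth_rate = numeric(), reason = character())
  }
  x
}

#' Split an assay table into per-replicate units
#'
#' @param x A validated assay tibble.
#' @return A named list of tibbles, one per replicate population, in
#'   replicate order.
#' @export
assay_units <- function(x) {
  x <- as_assay_data(x)
  split(x, factor(x$replicate_id, levels = unique(x$replicate_id)))
}
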