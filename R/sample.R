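#' Measure-valued samples
#'
#' An `rvvm_sample` holds the records produced by applying an independent
#' measurement protocol to a simple random sample: one measure per unit, plus
#' optional covariates and an optional gold-standard truth.  Records are
#' assumed mutually independent.
#'
#' @param measures a list of `rvvm_measure` objects, or a numeric vector
#'   (coerced to point masses), or a single measure (recycled is not allowed;
#'   supply a list).
#' @param truth optional numeric vector of gold-standard values (`NA` where
#'   unknown).  When a truth is present it must lie in the support of the
#'   unit's measure unless that unit is flagged in `measurement_error` (a
#'   trivial measurement not supported on the truth is classical measurement
#'   error, which this container only records, never models).
#' @param covariates optional data frame of per-unit covariates.
#' @param unit_id optional identifiers; defaults to `seq_len(n)`.
#' @param range_y optional declared support set for the target variable; when
#'   given, every measure's support must be a subset of it.
#' @param measurement_error logical vector flagging units whose truth is
#'   deliberately outside the measure's support.
#' @return An object of class `rvvm_sample`.
#' @examples
#' s <- rvvm_sample(list(point_mass(0), point_mass(1), bernoulli_measure(0.7)))
#' generalized_mean(s)
#' @export
rvvm_sample <- function(measures, truth = NULL, covariates = NULL,
                        unit_id = NULL, range_y = NULL,
                        measurement_error = FALSE) {
  if (is.numeric(measures))
    measures <- lapply(measures, point_mass)
  if (is_measure(measures))
    measures <- list(measures)
  if (!is.list(measures) || !all(vapply(measures, is_measure, TRUE)))
    stop("'measures' must be a list of rvvm_measure objects")
  n <- length(measures)
  if (is.null(unit_id)) unit_id <- seq_len(n)
  if (length(unit_id) != n) stop("'unit_id' has wrong length")
  if (!is.null(truth)) {
    if (length(truth) != n) stop("'truth' has wrong length")
    me <- rep_len(measurement_error, n)
    for (i in seq_len(n)) {
      if (!is.na(truth[i]) && !me[i] &&
          !truth[i] %in% measures[[i]]$support)
        stop(sprintf(paste0("truth %.6g of unit %s is outside the support of ",
                            "its measure; flag 'measurement_error' if intended"),
                     truth[i], unit_id[i]))
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("'covariates' has wrong number of rows")
  }
  if (!is.null(range_y)) {
    for (i in seq_len(n))
      if (!all(measures[[i]]$support %in% range_y))
        stop(sprintf("measure of unit %s charges values outside 'range_y'",
                     unit_id[i]))
  }
  structure(list(measures = measures, truth = truth, covariates = covariates,
                 unit_id = unit_id, range_y = range_y),
            class = "rvvm_sample")
}

#' @export
print.rvvm_sample <- function(x, ...) {
  n <- length(x$measures)
  k <- sum(!vapply(x$measures, is_point_mass, TRUE))
  cat(sprintf("<rvvm_sample> n = %d record%s (%d nontrivial)\n",
              n, if (n == 1) "" else "s", k))
  if (!is.null(x$truth))
    cat(sprintf("  gold-standard truth present for %d record%s\n",
                sum(!is.na(x$truth)), if (sum(!is.na(x$truth)) == 1) "" else "s"))
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.rvvm_sample <- function(x) length(x$measures)

#' Generalized sample mean and sum
#'
#' For a measure-valued sample the analogue of the sample mean is
#' \deqn{\bar\rho(S) = \frac1n \sum_{i=1}^n \int x \, d\mu_i(x),}
#' the average of the per-record expectations; when every measurement is a
#' point mass this is the ordinary sample mean.  Under a calibrated protocol
#' \eqn{\bar\rho(S)} is an unbiased, consistent estimator of \eqn{E(Y)}.
#' `generalized_sum()` returns \eqn{n \cdot \bar\rho(S)}, the analogue of the
#' sample sum (used, e.g., as a rating-scale total score).
#'
#' @param sample an `rvvm_sample` (or a list of measures) with at least one
#'   record.
#' @return A single number.
#' @examples
#' generalized_mean(rvvm_sample(c(0, 1)))                   # 0.5
#' generalized_sum(rvvm_sample(list(discrete_measure(0:4, c(0,.5,.5,0,0)))))
#' @export
generalized_mean <- function(sample) {
  ms <- sample_measures(sample)
  if (length(ms) == 0L) stop("empty sample")
  mean(vapply(ms, mean, 0))
}

#' @rdname generalized_mean
#' @export
generalized_sum <- function(sample) {
  ms <- sample_measures(sample)
  if (length(ms) == 0L) stop("empty sample")
  sum(vapply(ms, mean, 0))
}

sample_measures <- function(sample) {
  if (inherits(sample, "rvvm_sample")) return(sample$measures)
  if (is.list(sample) && all(vapply(sample, is_measure, TRUE))) return(sample)
  if (is.numeric(sample)) return(lapply(sample, point_mass))
  stop("expected an rvvm_sample, a list of measures, or a numeric vector")
}

## ---- CSV dialect ----------------------------------------------------------

#' Read and write the RVVM CSV dialect
#'
#' A UTF-8 CSV with a header row in which designated columns carry measure
#' literals (see [parse_measure()]) and a column named `<var>__truth` holds an
#' optional gold standard for the measured variable `<var>`.  Measure columns
#' are auto-detected (any column containing a `ber:` or `cat:` literal) unless
#' named explicitly.  In the returned data frame each measure column is a list
#' column of `rvvm_measure` objects.
#'
#' @param path file path.
#' @param measure_cols character vector of measure-column names, or `NULL` to
#'   auto-detect.
#' @param data a data frame whose measure columns are list columns of
#'   `rvvm_measure` objects (as produced by [read_rvvm_csv()] or
#'   [generate_birds()]).
#' @return `read_rvvm_csv()`: a data frame with measure list columns.
#'   `write_rvvm_csv()`: `invisible(path)`.
#' @export
read_rvvm_csv <- function(path, measure_cols = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("NA", ""))
  if (is.null(measure_cols)) {
    is_meas <- vapply(raw, function(col)
      any(grepl("^\\s*(ber|cat):", col[!is.na(col)])), TRUE)
    measure_cols <- names(raw)[is_meas]
  } else {
    missing_cols <- setdiff(measure_cols, names(raw))
    if (length(missing_cols))
      stop("measure columns not in file: ", paste(missing_cols, collapse = ", "))
  }
  out <- lapply(names(raw), function(nm) {
    col <- raw[[nm]]
    if (nm %in% measure_cols) {
      I(lapply(col, function(cell) if (is.na(cell)) NA else parse_measure(cell)))
    } else {
      num <- suppressWarnings(as.numeric(col))
      if (all(is.na(num) == is.na(col))) num else col
    }
  })
  names(out) <- names(raw)
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_rvvm_csv
#' @export
write_rvvm_csv <- function(data, path) {
  out <- data
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.list(col)) {
      out[[nm]] <- vapply(col, function(cell) {
        if (length(cell) == 1L && !is_measure(cell) && is.na(cell)) NA_character_
        else format_measure(cell)
      }, "")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

## Columns of a data frame that are measure list columns.
measure_columns <- function(data) {
  names(data)[vapply(data, function(col)
    is.list(col) && any(vapply(col, is_measure, TRUE)), TRUE)]
}
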