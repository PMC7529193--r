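#' Empirical calibration of a measurement protocol
#'
#' A protocol is calibrated when, for every measure \eqn{\mu} it can emit, the
#' expectation of \eqn{\mu} equals the mean of the truth over all units that
#' received exactly that measure (the set \eqn{O_\omega}).  Given a sample
#' with gold-standard truths, `calibration_groups()` partitions the records by
#' exact measure identity and `calibration_report()` compares each group's
#' measure expectation with its empirical truth mean.
#'
#' Exact grouping follows the definition; for sparse real data with
#' near-identical confidences, `bin_width` optionally pools Bernoulli measures
#' whose success probabilities fall in the same bin (a pragmatic extension,
#' flagged in the output).
#'
#' @param sample an `rvvm_sample` in which every record has a truth value.
#' @param bin_width optional width for binning Bernoulli confidences (e.g.
#'   0.05); `NULL` for exact grouping.
#' @param groups a data frame from `calibration_groups()`.
#' @return `calibration_groups()`: a data frame with one row per distinct
#'   measure — columns `measure` (literal), `count`, `expectation`,
#'   `empirical_mean`, `unit_ids` (list) — ordered by expectation.
#'   `calibration_report()`: an object of class `calibration_report` with the
#'   group table augmented by `discrepancy` and, for binary measures, exact
#'   two-sided binomial `p_value` and Holm-adjusted `p_holm`, plus fields
#'   `max_abs_discrepancy` and `weighted_mean_discrepancy`.  No accept/reject
#'   decision is made: thresholds for declaring a protocol calibrated are left
#'   to the analyst.
#' @examples
#' s <- rvvm_sample(rep(list(bernoulli_measure(0.9)), 10),
#'                  truth = c(rep(1, 9), 0))
#' calibration_report(calibration_groups(s))
#' @export
calibration_groups <- function(sample, bin_width = NULL) {
  stopifnot(inherits(sample, "rvvm_sample"))
  if (is.null(sample$truth) || anyNA(sample$truth)) {
    bad <- if (is.null(sample$truth)) sample$unit_id
           else sample$unit_id[is.na(sample$truth)]
    stop("calibration requires a truth for every record; missing for units: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  ms <- sample$measures
  if (!is.null(bin_width)) {
    ms <- lapply(ms, function(m) {
      if (identical(m$support, c(0, 1)) || is_point_mass(m) &&
          all(m$support %in% c(0, 1))) {
        th <- if (is_point_mass(m)) m$support else m$probs[2]
        bernoulli_measure(min(1, bin_width * (floor(th / bin_width + 1e-9) + 0.5)))
      } else m
    })
  }
  keys <- vapply(ms, measure_key, "")
  idx <- split(seq_along(keys), keys)
  rows <- lapply(idx, function(i) {
    m <- ms[[i[1]]]
    data.frame(measure = format_measure(m),
               count = length(i),
               expectation = mean(m),
               empirical_mean = mean(sample$truth[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$unit_ids <- I(lapply(idx, function(i) sample$unit_id[i]))
  out$binary <- vapply(idx, function(i) all(ms[[i[1]]]$support %in% c(0, 1)),
                       TRUE)
  out <- out[order(out$expectation), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "binned") <- !is.null(bin_width)
  out
}

#' @rdname calibration_groups
#' @export
calibration_report <- function(groups) {
  if (!is.data.frame(groups) || nrow(groups) == 0L)
    stop("'groups' must be a nonempty data frame from calibration_groups()")
  g <- groups
  g$discrepancy <- abs(g$expectation - g$empirical_mean)
  g$p_value <- NA_real_
  for (i in seq_len(nrow(g))) {
    if (isTRUE(g$binary[i])) {
      x <- round(g$empirical_mean[i] * g$count[i])
      g$p_value[i] <- stats::binom.test(x, g$count[i],
                                        p = g$expectation[i])$p.value
    }
  }
  tested <- !is.na(g$p_value)
  g$p_holm <- NA_real_
  g$p_holm[tested] <- stats::p.adjust(g$p_value[tested], method = "holm")
  structure(list(groups = g,
                 max_abs_discrepancy = max(g$discrepancy),
                 weighted_mean_discrepancy =
                   sum(g$count * g$discrepancy) / sum(g$count),
                 binned = isTRUE(attr(groups, "binned"))),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, digits = 4, ...) {
  cat("Calibration report",
      if (x$binned) " (binned Bernoulli confidences)" else "", "\n", sep = "")
  tab <- x$groups[, c("measure", "count", "expectation", "empirical_mean",
                      "discrepancy", "p_value", "p_holm")]
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("max |discrepancy| = %s;  count-weighted mean = %s\n",
              format(x$max_abs_discrepancy, digits = digits),
              format(x$weighted_mean_discrepancy, digits = digits)))
  invisible(x)
}
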