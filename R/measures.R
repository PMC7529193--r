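#' Discrete probability measures as sample measurements
#'
#' A random-variable-valued measurement (RVVM) records an observation not as a
#' fixed number but as a finitely supported Borel probability measure over the
#' possible values of the target variable.  `discrete_measure()` is the general
#' constructor; `point_mass()` builds the degenerate measure \eqn{\delta_x}
#' (a classical, "trivial" measurement) and `bernoulli_measure()` the measure
#' Ber(\eqn{\theta}) on \{0, 1\} used for binary assessments with stated
#' confidence \eqn{\theta}.
#'
#' Measures are stored in canonical form: support strictly increasing, atoms
#' with zero probability dropped, probabilities renormalized when their sum is
#' within `1e-9` of one (tolerant of decimal rounding in hand-entered files)
#' and rejected otherwise.
#'
#' @param support numeric vector of distinct, finite support points.
#' @param probs numeric vector of probabilities aligned with `support`.
#' @param x a finite real number.
#' @param theta success probability in \[0, 1\]; `theta` of 0 or 1 collapses to
#'   a point mass on the charged atom.
#' @return An object of class `rvvm_measure`: a list with numeric fields
#'   `support` and `probs`.
#' @examples
#' m <- bernoulli_measure(0.9)
#' mean(m)
#' variance(m)
#' point_mass(7.5)
#' discrete_measure(0:4, c(0, 0.5, 0.5, 0, 0))
#' @export
discrete_measure <- function(support, probs) {
  if (!is.numeric(support) || !is.numeric(probs))
    stop("'support' and 'probs' must be numeric")
  if (length(support) != length(probs))
    stop("'support' and 'probs' must have equal length")
  if (length(support) == 0L)
    stop("a measure needs at least one support point")
  if (any(!is.finite(support)))
    stop("support values must be finite")
  if (any(!is.finite(probs)) || any(probs < -1e-12) || any(probs > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  s <- sum(probs)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("probabilities sum to %.12g, not 1 (tolerance 1e-9)", s))
  probs <- probs / s
  keep <- probs > 0
  support <- support[keep]
  probs <- probs[keep]
  o <- order(support)
  support <- support[o]
  probs <- probs[o]
  if (anyDuplicated(support))
    stop("support values must be distinct")
  structure(list(support = support, probs = probs), class = "rvvm_measure")
}

#' @rdname discrete_measure
#' @export
point_mass <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'x' must be a single finite number")
  structure(list(support = as.numeric(x), probs = 1), class = "rvvm_measure")
}

#' @rdname discrete_measure
#' @export
bernoulli_measure <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1)
    stop("'theta' must be a single probability in [0, 1]")
  discrete_measure(c(0, 1), c(1 - theta, theta))
}

#' @export
print.rvvm_measure <- function(x, ...) {
  cat("<measure> ", format_measure(x), "\n", sep = "")
  invisible(x)
}

#' Test for measure objects and point masses
#'
#' @param x an object.
#' @param m an `rvvm_measure`.
#' @return `is_measure()`: logical. `is_point_mass()`: `TRUE` iff the measure
#'   places probability one on a single support point.
#' @export
is_measure <- function(x) inherits(x, "rvvm_measure")

#' @rdname is_measure
#' @export
is_point_mass <- function(m) {
  stopifnot(is_measure(m))
  length(m$support) == 1L
}

#' Moments of a discrete measure
#'
#' `mean()` returns \eqn{\int x \, d\mu(x) = \sum_i p_i x_i}, the expectation
#' of a random variable \eqn{Z \sim \mu}.  `variance()` is the corresponding
#' second central moment, zero exactly for point masses.
#'
#' @param x,object an `rvvm_measure` (or, for `variance()`, any object with a
#'   method).
#' @param ... unused.
#' @export
mean.rvvm_measure <- function(x, ...) sum(x$support * x$probs)

#' @rdname mean.rvvm_measure
#' @export
variance <- function(object, ...) UseMethod("variance")

#' @rdname mean.rvvm_measure
#' @export
variance.rvvm_measure <- function(object, ...) {
  mu <- sum(object$support * object$probs)
  max(0, sum(object$probs * object$support^2) - mu^2)
}

#' Information content of a measurement at the truth
#'
#' For a nontrivial measurement \eqn{\mu} of a unit whose true value is
#' \eqn{y}, the Kullback-Leibler divergence from \eqn{\mu} to the point mass
#' \eqn{\delta_y} reduces to \eqn{-\log \mu(\{y\})}: the information (in nats)
#' lost by measuring with \eqn{\mu} instead of observing \eqn{y} directly.
#' It is nonnegative, and zero exactly when \eqn{\mu = \delta_y}.
#'
#' @param m an `rvvm_measure`.
#' @param y_true the unit's true value; must carry positive probability under
#'   `m` (otherwise the divergence is infinite and an error is raised, since
#'   the protocol excludes the truth).
#' @return Nonnegative number, in nats.
#' @examples
#' information_content(bernoulli_measure(0.9), 1) # -log(0.9)
#' information_content(point_mass(1), 1)          # 0
#' @export
information_content <- function(m, y_true) {
  stopifnot(is_measure(m))
  if (!is.numeric(y_true) || length(y_true) != 1L || !is.finite(y_true))
    stop("'y_true' must be a single finite number")
  idx <- match(y_true, m$support)
  if (is.na(idx) || m$probs[idx] <= 0)
    stop("measure assigns zero probability to the true value: ",
         "infinite divergence (the protocol excludes the truth)")
  -log(m$probs[idx])
}

## ---- measure literals -----------------------------------------------------
## Grammar for one CSV cell:
##   <number>                      point mass
##   ber:<p>                       Bernoulli measure on {0, 1}
##   cat:<v1>:<p1>,<v2>:<p2>,...   general categorical measure

#' Parse and serialize measure literals
#'
#' The plain-text encoding used in the RVVM CSV dialect: a bare numeral is a
#' point mass (so any classical dataset is a valid RVVM dataset unchanged),
#' `ber:<p>` is a Bernoulli measure, and `cat:<v1>:<p1>,<v2>:<p2>,...` a
#' general categorical measure.  `format_measure()` emits the canonical
#' literal; `parse_measure()` inverts it.  Probabilities whose sum is within
#' `1e-9` of one are renormalized; anything further off is a parse error.
#'
#' @param text a single measure-literal string.
#' @param m an `rvvm_measure`.
#' @return `parse_measure()`: an `rvvm_measure`. `format_measure()`: a string.
#' @examples
#' parse_measure("ber:0.9")
#' parse_measure("1")
#' format_measure(discrete_measure(0:4, c(0, 0.5, 0.5, 0, 0)))
#' @export
parse_measure <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single string")
  txt <- trimws(text)
  if (grepl("^ber:", txt)) {
    p <- suppressWarnings(as.numeric(sub("^ber:", "", txt)))
    if (is.na(p) || p < 0 || p > 1)
      stop("malformed Bernoulli literal: ", text)
    return(bernoulli_measure(p))
  }
  if (grepl("^cat:", txt)) {
    body <- sub("^cat:", "", txt)
    pairs <- strsplit(body, ",", fixed = TRUE)[[1]]
    parts <- strsplit(pairs, ":", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed categorical literal: ", text)
    v <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    p <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (any(is.na(v)) || any(is.na(p)))
      stop("malformed categorical literal: ", text)
    if (abs(sum(p) - 1) > 1e-9)
      stop(sprintf("categorical literal probabilities sum to %.12g, not 1: %s",
                   sum(p), text))
    return(discrete_measure(v, p))
  }
  x <- suppressWarnings(as.numeric(txt))
  if (is.na(x))
    stop("malformed measure literal: ", text)
  point_mass(x)
}

#' @rdname parse_measure
#' @export
format_measure <- function(m) {
  stopifnot(is_measure(m))
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  if (is_point_mass(m))
    return(num(m$support))
  if (identical(m$support, c(0, 1)))
    return(paste0("ber:", num(m$probs[2])))
  paste0("cat:", paste0(num(m$support), ":", num(m$probs), collapse = ","))
}

## Exact-identity key for grouping by measure (full double precision).
measure_key <- function(m) {
  paste(sprintf("%.17g", c(m$support, m$probs)), collapse = "|")
}
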