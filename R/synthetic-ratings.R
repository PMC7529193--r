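#' Simulate clinician rating-scale data with per-category confidences
#'
#' Emulates a 17-item depression rating instrument scored by a clinician who,
#' instead of committing to a single category per item, reports a confidence
#' over the five integer categories 0-4: a categorical random-variable-valued
#' measurement.  Each patient has a latent severity; each item perturbs it,
#' the perturbed value is cut into a modal category, and the reported
#' confidence vector is a Dirichlet draw concentrated on that modal category
#' (`concentration` controls how peaked; `Inf` gives exact point masses, the
#' classical protocol).  The classical companion protocol (`rho1`, the modal
#' category as a point mass) is returned alongside the confidence protocol
#' (`rho2`).
#'
#' @param n_patients,n_items dimensions (both at least 1).
#' @param category_scores ascending integer scores (default 0:4).
#' @param concentration Dirichlet concentration on the modal category;
#'   `Inf` collapses every measure to a point mass.
#' @param item_sd standard deviation of the per-item perturbation of the
#'   latent severity.
#' @param seed integer seed.
#' @return A data frame with columns `patient`, `item`, `rho1` (modal score)
#'   and the measure list column `rho2`.
#' @examples
#' r <- generate_ratings(n_patients = 2, n_items = 3, seed = 1)
#' generalized_sum(r$rho2[r$patient == 1])
#' @export
generate_ratings <- function(n_patients, n_items = 17, category_scores = 0:4,
                             concentration = 10, item_sd = 0.5, seed = NULL) {
  if (n_patients < 1 || n_items < 1)
    stop("'n_patients' and 'n_items' must be at least 1")
  if (is.unsorted(category_scores, strictly = TRUE))
    stop("'category_scores' must be strictly ascending")
  if (!is.null(seed)) set.seed(seed)
  k <- length(category_scores)
  # cutpoints put equal marginal mass on each category for the latent scale
  cuts <- stats::qnorm(seq_len(k - 1) / k, sd = sqrt(1 + item_sd^2))
  severity <- stats::rnorm(n_patients)
  out <- vector("list", n_patients * n_items)
  rho1 <- numeric(n_patients * n_items)
  row <- 0L
  for (p in seq_len(n_patients)) {
    latent <- severity[p] + stats::rnorm(n_items, 0, item_sd)
    modal <- findInterval(latent, cuts) + 1L
    for (it in seq_len(n_items)) {
      row <- row + 1L
      rho1[row] <- category_scores[modal[it]]
      if (is.infinite(concentration)) {
        out[[row]] <- point_mass(category_scores[modal[it]])
      } else {
        alpha <- rep(0.5, k)
        alpha[modal[it]] <- alpha[modal[it]] + concentration
        g <- stats::rgamma(k, alpha)
        out[[row]] <- discrete_measure(category_scores, g / sum(g))
      }
    }
  }
  res <- data.frame(patient = rep(seq_len(n_patients), each = n_items),
                    item = rep(seq_len(n_items), n_patients),
                    rho1 = rho1)
  res$rho2 <- I(out)
  res
}

#' Depressed-mood item confidences for eight example patients
#'
#' The fixed first-item encoding of the rating-scale worked example: for each
#' of 8 patients, the classical single-category score (`rho1`) and the
#' clinician's confidence vector over categories 0-4 (`rho2`).  The total
#' score under the confidence protocol is the generalized sum
#' \eqn{n \cdot \bar\rho(S)} over a patient's items.
#'
#' @return A data frame with columns `patient`, `rho1` and the measure list
#'   column `rho2`.
#' @examples
#' h <- hamd_item1_example()
#' mean(h$rho2[[1]])   # 1.5: leaning beyond the recorded score of 1
#' @export
hamd_item1_example <- function() {
  vecs <- list(c(0, 0.5, 0.5, 0, 0),
               c(0, 1, 0, 0, 0),
               c(0, 0.1, 0.6, 0.3, 0),
               c(0, 0.1, 0.8, 0.1, 0),
               c(0, 0.7, 0.3, 0, 0),
               c(0, 0, 0, 0.8, 0.2),
               c(0, 0.1, 0.9, 0, 0),
               c(0, 0.6, 0.4, 0, 0))
  out <- data.frame(patient = 1:8,
                    rho1 = c(1, 1, 2, 2, 1, 3, 2, 1))
  out$rho2 <- I(lapply(vecs, function(v) discrete_measure(0:4, v)))
  out
}
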