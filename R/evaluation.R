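#' Exact expected precision of a random window placement
#'
#' Closed-form expectation of base-level precision when an L bp predicted
#' window and an L bp true rewrite window are placed independently and
#' uniformly over all valid starts of an N bp promoter. Precision of a single
#' draw is the overlap fraction |pred ∩ true| / L; the expectation enumerates
#' all (N - L + 1)^2 start pairs exactly:
#'
#' \deqn{E = \sum_{s_1, s_2} \max(0, L - |s_1 - s_2|) / (L (M+1)^2), \quad M = N - L.}
#'
#' For the defaults used throughout the package (N = 400), this gives
#' ~0.01258 for L = 5 and ~0.107 for L = 40: the geometric floor any
#' position-blind predictor is compared against.
#'
#' @param N Promoter length in bases.
#' @param L Window length in bases (the model-specific rewriting length).
#' @return Exact expected precision as a proportion in \[0, 1\].
#' @seealso [random_baseline_precision()] for the Monte-Carlo estimator.
#' @export
#' @examples
#' expected_precision_closed_form(400, 5)   # ~0.0126
#' expected_precision_closed_form(400, 40)  # ~0.107
expected_precision_closed_form <- function(N, L) {
  stopifnot(is.numeric(N), is.numeric(L), length(N) == 1L, length(L) == 1L)
  if (L > N) stop("window length L must not exceed promoter length N")
  M <- N - L
  d <- abs(outer(0:M, 0:M, "-"))
  sum(pmax(0, L - d)) / (L * (M + 1)^2)
}

#' Monte-Carlo random-placement precision baseline
#'
#' Estimates the expected base-level precision of uniformly random L bp
#' window placements against independently uniform L bp true windows in an
#' N bp promoter. Optionally, starts whose window would overlap any
#' `avoid_regions` interval (e.g. an annotated TATA-box or TSS) are excluded
#' for both the predicted and the true window, mirroring how screening
#' avoids essential elements.
#'
#' @param N Promoter length in bases (default 400).
#' @param L Window length in bases (5 or 40 in the two-stage system).
#' @param n_samples Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; the estimate is reproducible for a fixed seed.
#' @param avoid_regions Optional list of 0-based half-open intervals
#'   (two-element numeric vectors) that windows must not overlap.
#' @return A list with `estimate` (proportion), `se` (Monte-Carlo standard
#'   error), `n_samples`, and `n_allowed_starts`.
#' @export
#' @examples
#' b <- random_baseline_precision(400, 5, n_samples = 1e5, seed = 1)
#' b$estimate * 100  # prints as ~1.26 (%)
random_baseline_precision <- function(N = 400, L, n_samples, seed,
                                      avoid_regions = NULL) {
  stopifnot(L <= N, n_samples >= 1)
  starts <- 0:(N - L)
  if (!is.null(avoid_regions)) {
    ok <- rep(TRUE, length(starts))
    for (iv in avoid_regions) {
      stopifnot(length(iv) == 2L, iv[1] <= iv[2])
      # window [s, s+L) overlaps [a, b) iff s < b and s + L > a
      ok <- ok & !(starts < iv[2] & starts + L > iv[1])
    }
    starts <- starts[ok]
  }
  if (length(starts) == 0L)
    stop("no allowed window starts remain after applying avoid_regions")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  s1 <- sample(starts, n_samples, replace = TRUE)
  s2 <- sample(starts, n_samples, replace = TRUE)
  frac <- pmax(0, L - abs(s1 - s2)) / L
  list(estimate = mean(frac),
       se = stats::sd(frac) / sqrt(n_samples),
       n_samples = n_samples,
       n_allowed_starts = length(starts))
}

#' Base-level precision and recall of a predicted position set
#'
#' Scores a set of predicted positive positions against a true rewrite
#' window. Precision is |pred ∩ true| / |pred| and is undefined (NA) when
#' the prediction set is empty; such cases are excluded from averages by
#' [evaluate_placeback()]. Recall is |pred ∩ true| / L, the fraction of the
#' rewrite window recovered.
#'
#' @param pred_positions Integer vector of 0-based predicted positions.
#' @param true_window 0-based half-open interval `c(start, end)` of the true
#'   rewrite window.
#' @param L Rewrite window length; defaults to `diff(true_window)`.
#' @return Named numeric vector `c(precision = , recall = )`; precision is
#'   `NA` for an empty prediction set.
#' @export
base_precision_recall <- function(pred_positions, true_window,
                                  L = diff(true_window)) {
  stopifnot(length(true_window) == 2L, true_window[1] <= true_window[2])
  pred_positions <- unique(as.integer(pred_positions))
  hits <- sum(pred_positions >= true_window[1] & pred_positions < true_window[2])
  precision <- if (length(pred_positions) == 0L) NA_real_ else hits / length(pred_positions)
  c(precision = precision, recall = hits / L)
}

# Seed the session RNG locally, returning the previous state so callers can
# restore it; keeps seeded package functions from clobbering the user's RNG.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
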