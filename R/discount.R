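#' Discounting configuration
#'
#' Thresholds and decrements governing data-driven discounting of MS
#' evidence. Defaults are the operating values used throughout:
#' precursor ions heavier than `T_mass` = 4000 Da fragment poorly, so
#' their evidence loses `alpha_mass` = 0.1 of weight; matches whose
#' abundance-significance score pp2 falls below `T_pp` = 50 lose
#' `alpha_pp` = 0.2.
#'
#' @param T_mass precursor-mass threshold in Daltons.
#' @param T_pp pp2 score threshold.
#' @param alpha_mass weight decrement applied above `T_mass`.
#' @param alpha_pp weight decrement applied below `T_pp`.
#' @return A `discount_config` list.
#' @export
discount_config <- function(T_mass = 4000, T_pp = 50,
                            alpha_mass = 0.1, alpha_pp = 0.2) {
  if (T_mass <= 0 || T_pp <= 0) stop("thresholds must be > 0", call. = FALSE)
  if (alpha_mass < 0 || alpha_mass > 1 || alpha_pp < 0 || alpha_pp > 1) {
    stop("decrements must lie in [0, 1]", call. = FALSE)
  }
  structure(list(T_mass = T_mass, T_pp = T_pp,
                 alpha_mass = alpha_mass, alpha_pp = alpha_pp),
            class = "discount_config")
}

new_discount_weights <- function(method, alpha) {
  alpha <- min(max(alpha, 0), 1)
  structure(list(method = method, alpha = alpha),
            class = "discount_weights")
}

#' Reliability weight constructor
#'
#' @param method source tag.
#' @param alpha reliability in \[0, 1\].
#' @return A `discount_weights` object.
#' @export
discount_weights <- function(method, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  new_discount_weights(method, alpha)
}

#' Data-driven reliability weight for MS evidence
#'
#' The weight starts at 1 (no discounting). It is decreased by
#' `alpha_mass` when the precursor ion mass exceeds `T_mass` (large ions
#' fragment poorly) and further decreased by `alpha_pp` when the pp2
#' abundance-significance score falls below `T_pp` (the matched peaks
#' could plausibly be low-abundance noise). Decrements are subtractive
#' and the weight is floored at 0.
#'
#' @param precursor_mass precursor ion mass in Daltons.
#' @param pp2 abundance-significance score (see [pp2_score()]).
#' @param cfg a [discount_config()].
#' @return A `discount_weights` object with method `"MS"`.
#' @export
discount_ms <- function(precursor_mass, pp2, cfg = discount_config()) {
  if (precursor_mass <= 0) stop("precursor_mass must be > 0", call. = FALSE)
  w <- 1
  if (precursor_mass > cfg$T_mass) w <- w - cfg$alpha_mass
  if (pp2 < cfg$T_pp) w <- w - cfg$alpha_pp
  new_discount_weights("MS", w)
}

#' Empirical reliability weight for SVM evidence
#'
#' The weight starts equal to the belief score. Mid-range beliefs
#' (between 0.5 and 0.9, exclusive) are divided by 1.5; beliefs of 0.5 or
#' lower are divided by 3. A belief of exactly 0.9 keeps its full value.
#'
#' @param belief SVM belief score in \[0, 1\].
#' @return A `discount_weights` object with method `"SVM"`.
#' @export
discount_svm <- function(belief) {
  if (!is.finite(belief) || belief < 0 || belief > 1) {
    stop("belief must lie in [0, 1]", call. = FALSE)
  }
  w <- if (belief >= 0.9) belief else if (belief > 0.5) belief / 1.5
       else belief / 3
  new_discount_weights("SVM", w)
}

#' Empirical reliability weight for CSP evidence
#'
#' The weight starts at 1. A divergence D above 10 costs D/100; having
#' fewer than two reference profiles tied at the minimal divergence costs
#' a further 0.1 (a unique nearest neighbour gives no corroboration).
#' The weight is floored at 0.
#'
#' @param divergence divergence D of the best profile match.
#' @param n_best_matches number of reference entries tied at minimal D.
#' @return A `discount_weights` object with method `"CSP"`.
#' @export
discount_csp <- function(divergence, n_best_matches) {
  if (divergence < 0) stop("divergence must be >= 0", call. = FALSE)
  if (n_best_matches < 0) stop("n_best_matches must be >= 0", call. = FALSE)
  w <- 1
  if (divergence > 10) w <- w - divergence / 100
  if (n_best_matches < 2) w <- w - 0.1
  new_discount_weights("CSP", w)
}
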