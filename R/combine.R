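# n-ary product core shared by the combination rules.
#
# Folds the sources left to right, accumulating the product mass of every
# tuple of focal elements (one per source, the environment counting as an
# element) onto the intersection of the tuple. Because set intersection is
# associative and products distribute, the fold equals the simultaneous
# n-ary combination; mass landing on the empty set is pooled as conflict.
# Two different bonds sharing a cysteine are distinct set elements, so
# their intersection is empty (conflict), consistent with the rule that
# bond sets sharing a cysteine are inconsistent.
cross_products <- function(masses) {
  stopifnot(length(masses) >= 2L)
  acc_focal <- masses[[1L]]$mass        # named by focal key
  acc_sets <- masses[[1L]]$focal
  acc_env <- masses[[1L]]$environment
  conflict <- 0
  for (s in 2L:length(masses)) {
    m <- masses[[s]]
    new_focal <- numeric(0)
    new_sets <- list()
    new_env <- acc_env * m$environment
    # focal x focal
    for (ka in names(acc_focal)) {
      for (kb in names(m$mass)) {
        inter <- intersect(acc_sets[[ka]], m$focal[[kb]])
        p <- acc_focal[[ka]] * m$mass[[kb]]
        if (length(inter) == 0L) {
          conflict <- conflict + p
        } else {
          ki <- focal_key(inter)
          if (is.null(new_sets[[ki]])) new_sets[[ki]] <- sort_bonds(inter)
          new_focal[ki] <- if (ki %in% names(new_focal))
            new_focal[[ki]] + p else p
        }
      }
    }
    # environment x focal (environment intersects everything)
    for (kb in names(m$mass)) {
      p <- acc_env * m$mass[[kb]]
      if (p > 0) {
        if (is.null(new_sets[[kb]])) new_sets[[kb]] <- m$focal[[kb]]
        new_focal[kb] <- if (kb %in% names(new_focal))
          new_focal[[kb]] + p else p
      }
    }
    for (ka in names(acc_focal)) {
      p <- acc_focal[[ka]] * m$environment
      if (p > 0) {
        if (is.null(new_sets[[ka]])) new_sets[[ka]] <- acc_sets[[ka]]
        new_focal[ka] <- if (ka %in% names(new_focal))
          new_focal[[ka]] + p else p
      }
    }
    acc_focal <- new_focal
    acc_sets <- new_sets
    acc_env <- new_env
  }
  list(focal = acc_focal, sets = acc_sets, environment = acc_env,
       conflict = conflict)
}

new_combination_result <- function(fused, conflict_mass, rule) {
  conflict_weight <- if (conflict_mass < 1) -log1p(-conflict_mass) else Inf
  structure(
    list(fused = fused, conflict_mass = conflict_mass,
         conflict_weight = conflict_weight, rule = rule),
    class = "combination_result"
  )
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("<combination_result> rule = %s, conflict = %.4f, log-weight = %.4f\n",
              x$rule, x$conflict_mass, x$conflict_weight))
  print(x$fused)
  invisible(x)
}

#' Combine mass functions with the Dempster rule
#'
#' The orthogonal sum: product mass of every tuple of focal elements (one
#' per source) accrues to the tuple's intersection, conflicting (empty)
#' intersections are discarded, and the remainder is renormalized. The
#' discarded fraction k is reported as `conflict_mass` and
#' `log(1/(1 - k))` (natural log) as the weight of conflict. Total
#' conflict (k = 1) is an error: the rule is undefined there.
#'
#' @param masses list of two or more [mass_function()] objects over the
#'   same frame.
#' @return A `combination_result`: list with `fused` (a [mass_function()]),
#'   `conflict_mass`, `conflict_weight`, `rule`.
#' @export
combine_dempster <- function(masses) {
  cp <- cross_products(masses)
  denom <- 1 - cp$conflict
  if (denom <= 1e-12) {
    stop("total conflict: the Dempster rule is undefined (k = 1)",
         call. = FALSE)
  }
  fused <- mass_function(unname(cp$sets[names(cp$focal)]),
                         cp$focal / denom,
                         environment_mass = cp$environment / denom)
  new_combination_result(fused, cp$conflict, "dempster")
}

#' Combine mass functions with the Yager rule
#'
#' Same products as the Dempster rule but without renormalization: all
#' conflicting product mass is attributed to the environment (the
#' universal set), enlarging ignorance instead of inflating agreement.
#' Total conflict is representable (the environment gets everything).
#' Only the simultaneous n-ary form is provided; the pairwise-iterated
#' form is order-dependent.
#'
#' @inheritParams combine_dempster
#' @return A `combination_result`.
#' @export
combine_yager <- function(masses) {
  cp <- cross_products(masses)
  fused <- mass_function(unname(cp$sets[names(cp$focal)]),
                         cp$focal,
                         environment_mass = cp$environment + cp$conflict)
  new_combination_result(fused, cp$conflict, "yager")
}

#' Combine mass functions with the Campos rule
#'
#' De-rates the Dempster orthogonal sum by the weight of conflict: every
#' fused mass is divided by (1 + log(X)) with X = 1/(1 - k), and the
#' deficit is assigned to the environment. With zero conflict this equals
#' the Dempster rule; with total conflict the weight diverges and an error
#' is raised.
#'
#' @inheritParams combine_dempster
#' @return A `combination_result`.
#' @export
combine_campos <- function(masses) {
  d <- combine_dempster(masses)
  w <- 1 + d$conflict_weight
  mass <- d$fused$mass / w
  fused <- mass_function(unname(d$fused$focal), mass,
                         environment_mass = 1 - sum(mass))
  new_combination_result(fused, d$conflict_mass, "campos")
}

# discount a source by reliability alpha: non-environment mass is scaled
# by alpha and the complement joins the environment
discount_mass <- function(m, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("discount weight must lie in [0, 1]", call. = FALSE)
  }
  mass_function(unname(m$focal), m$mass * alpha,
                environment_mass = 1 - alpha * (1 - m$environment))
}

#' Combine mass functions with the Shafer discount-and-average rule
#'
#' Each source is first discounted by its reliability weight alpha (its
#' focal masses scaled by alpha, the remainder moved to the environment),
#' then the discounted sources are averaged focal set by focal set. The
#' plain arithmetic mean is used. No conflict mass is discarded, so
#' `conflict_mass` is 0.
#'
#' @inheritParams combine_dempster
#' @param weights numeric vector of reliability weights in \[0, 1\], one per
#'   source (default all 1 = no discounting), or a list of
#'   [discount_weights()] objects.
#' @return A `combination_result`.
#' @export
combine_shafer <- function(masses, weights = rep(1, length(masses))) {
  if (is.list(weights)) {
    weights <- vapply(weights, function(w) w$alpha, numeric(1))
  }
  if (length(weights) != length(masses)) {
    stop("need one discount weight per source", call. = FALSE)
  }
  disc <- Map(discount_mass, masses, weights)
  keys <- unique(unlist(lapply(disc, function(m) names(m$mass))))
  sets <- list()
  for (m in disc) for (k in names(m$focal)) sets[[k]] <- m$focal[[k]]
  n <- length(disc)
  mass <- vapply(keys, function(k) {
    sum(vapply(disc, function(m) {
      if (k %in% names(m$mass)) m$mass[[k]] else 0
    }, numeric(1))) / n
  }, numeric(1))
  env <- sum(vapply(disc, function(m) m$environment, numeric(1))) / n
  fused <- mass_function(unname(sets[keys]), mass, environment_mass = env)
  new_combination_result(fused, 0, "shafer")
}

#' Per-bond fused beliefs from a combination result
#'
#' The score of a bond is the containment sum: total fused mass of the
#' focal sets that contain it (the environment excluded). This is the
#' per-bond value reported by the pipeline.
#'
#' @param result a `combination_result` from one of the `combine_*` rules.
#' @return Named numeric vector, one entry per bond appearing in any focal
#'   set, in bond order.
#' @export
bond_scores <- function(result) {
  fused <- result$fused
  bonds <- sort_bonds(unique(unlist(fused$focal)))
  out <- vapply(bonds, function(b) {
    inb <- vapply(fused$focal, function(f) b %in% f, logical(1))
    sum(fused$mass[inb])
  }, numeric(1))
  names(out) <- bonds
  out
}
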