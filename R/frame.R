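#' Build a frame of discernment
#'
#' The frame collects the primitive hypotheses (candidate bonds) over which
#' belief is assigned. In `"union"` mode (the default, used by the case
#' studies) the frame is the union of bonds reported by any method; in
#' `"all-pairs"` mode it is every cysteine pair of the protein, which
#' requires `protein`.
#'
#' @param evidence_sets list of [evidence_set()] objects for one protein.
#' @param mode `"union"` or `"all-pairs"`.
#' @param protein an [ss_protein()]; required for `"all-pairs"` mode.
#' @return Object of class `ss_frame`: list with `protein_id`,
#'   `hypotheses` (sorted bond keys), `mode`.
#' @export
build_frame <- function(evidence_sets, mode = c("union", "all-pairs"),
                        protein = NULL) {
  mode <- match.arg(mode)
  if (inherits(evidence_sets, "evidence_set")) {
    evidence_sets <- list(evidence_sets)
  }
  ids <- unique(vapply(evidence_sets, `[[`, character(1), "protein_id"))
  if (length(ids) > 1L) {
    stop("evidence sets refer to different proteins: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  if (mode == "union") {
    hyp <- unique(unlist(lapply(evidence_sets, function(e) e$items$bond)))
    if (length(hyp) == 0L) {
      stop("no bonds reported by any method; cannot build a union frame",
           call. = FALSE)
    }
  } else {
    if (is.null(protein)) {
      stop("all-pairs mode needs the protein record", call. = FALSE)
    }
    hyp <- all_pairs(protein)
  }
  structure(
    list(protein_id = if (length(ids)) ids else NA_character_,
         hypotheses = sort_bonds(hyp), mode = mode),
    class = "ss_frame"
  )
}

#' @export
print.ss_frame <- function(x, ...) {
  cat(sprintf("<ss_frame> %s (%s): %d hypotheses\n", x$protein_id, x$mode,
              length(x$hypotheses)))
  cat(" ", paste(x$hypotheses, collapse = "  "), "\n")
  invisible(x)
}

# key for a focal set: member bonds in numeric order joined by "+"
focal_key <- function(bonds) paste(sort_bonds(bonds), collapse = "+")

focal_bonds <- function(key) {
  if (identical(key, "")) character(0) else
    strsplit(key, "+", fixed = TRUE)[[1L]]
}

#' Enumerate consistent focal subsets of a frame
#'
#' Subsets of the hypotheses whose bonds form a matching (no shared
#' cysteine), up to a cardinality cap. Inconsistent subsets carry zero mass
#' by definition and are never materialized.
#'
#' @param frame an [build_frame()] result.
#' @param max_card largest subset cardinality to enumerate (default 4,
#'   the most simultaneous bonds the combination step considers).
#' @return List of character vectors of bond keys, ordered by cardinality
#'   then bond order; each is a valid focal set.
#' @export
enumerate_consistent_subsets <- function(frame, max_card = 4L) {
  max_card <- as.integer(max_card)
  if (max_card < 1L) stop("max_card must be >= 1", call. = FALSE)
  hyp <- frame$hypotheses
  n <- length(hyp)
  pos <- bond_positions(hyp)
  # grow matchings one bond at a time, only appending later-indexed bonds
  res <- list()
  grow <- function(members, used, start) {
    if (length(members) > 0L) res[[length(res) + 1L]] <<- hyp[members]
    if (length(members) >= max_card || start > n) return(invisible())
    for (i in start:n) {
      a <- pos[i, 1L]; b <- pos[i, 2L]
      if (!(a %in% used) && !(b %in% used)) {
        grow(c(members, i), c(used, a, b), i + 1L)
      }
    }
    invisible()
  }
  grow(integer(0), integer(0), 1L)
  res[order(lengths(res))]
}

#' Basic belief assignment (mass function)
#'
#' A mass function distributes unit belief over focal subsets of the frame
#' plus the environment (the universal set, representing ignorance).
#' Constraints: the empty set gets no mass, all masses are non-negative,
#' and masses including the environment sum to one.
#'
#' @param focal list of character vectors of bond keys (the focal sets).
#' @param mass numeric vector of masses, parallel to `focal`.
#' @param environment_mass mass assigned to the environment.
#' @param tol tolerance on the unit-sum check.
#' @return Object of class `mass_function` with fields `focal` (named list),
#'   `mass` (named numeric) and `environment`. Zero-mass focal sets are
#'   dropped.
#' @export
mass_function <- function(focal, mass, environment_mass = 0,
                          tol = 1e-9) {
  if (length(focal) != length(mass)) {
    stop("focal and mass must have equal length", call. = FALSE)
  }
  mass <- as.numeric(mass)
  if (any(mass < -tol) || environment_mass < -tol) {
    stop("masses must be non-negative", call. = FALSE)
  }
  if (any(lengths(focal) == 0L)) {
    stop("the empty set cannot be a focal set", call. = FALSE)
  }
  keys <- vapply(focal, focal_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate focal set(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "),
         call. = FALSE)
  }
  total <- sum(mass) + environment_mass
  if (abs(total - 1) > tol) {
    stop(sprintf("masses sum to %.12g, not 1", total), call. = FALSE)
  }
  keep <- mass > 0
  focal <- lapply(focal[keep], sort_bonds)
  mass <- mass[keep]
  keys <- keys[keep]
  names(focal) <- keys
  names(mass) <- keys
  structure(list(focal = focal, mass = mass,
                 environment = max(environment_mass, 0)),
            class = "mass_function")
}

#' @export
print.mass_function <- function(x, ...) {
  cat("<mass_function>\n")
  for (k in names(x$mass)) {
    cat(sprintf("  m{%s} = %.4f\n", k, x$mass[[k]]))
  }
  cat(sprintf("  m{environment} = %.4f\n", x$environment))
  invisible(x)
}

# raw subset score: mean over member bonds of (2*sigma + gamma - 1),
# clamped below at 0. gamma rewards uniformly confident subsets and
# penalizes subsets containing an unreported bond (sigma = 0).
raw_subset_score <- function(sigma) {
  k <- length(sigma)
  gamma <- if (any(sigma == 0)) -sum(sigma) / (2 * k) else sum(sigma) / (4 * k)
  max(sum(2 * sigma + gamma - 1) / k, 0)
}

#' Convert one method's bond beliefs into a mass function
#'
#' Each consistent subset j with member beliefs sigma_1..sigma_k receives a
#' raw score max(mean_i(2 sigma_i + gamma - 1), 0), where gamma is
#' -sum(sigma)/2k when any member is unreported (sigma = 0) and
#' +sum(sigma)/4k otherwise, so extreme beliefs (zero or near-one) shift
#' the score more than middling ones. Raw scores are then normalized: if
#' they total more than one they are scaled to sum to one (environment
#' mass zero); otherwise they are kept and the deficit becomes environment
#' mass.
#'
#' @param frame an [build_frame()] result.
#' @param evidence an [evidence_set()]; frame bonds the method did not
#'   report enter with belief 0.
#' @param subsets focal subsets from [enumerate_consistent_subsets()];
#'   computed from `frame` when omitted.
#' @param max_card passed to [enumerate_consistent_subsets()] when
#'   `subsets` is omitted.
#' @return A [mass_function()].
#' @export
assign_masses <- function(frame, evidence, subsets = NULL, max_card = 4L) {
  extra <- setdiff(evidence$items$bond, frame$hypotheses)
  if (length(extra) > 0L) {
    stop("evidence bond(s) absent from frame: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(subsets)) {
    subsets <- enumerate_consistent_subsets(frame, max_card = max_card)
  }
  raw <- vapply(subsets, function(s) {
    raw_subset_score(evidence_belief(evidence, s))
  }, numeric(1))
  total <- sum(raw)
  if (total > 1) {
    mass_function(subsets, raw / total, environment_mass = 0)
  } else {
    mass_function(subsets, raw, environment_mass = 1 - total)
  }
}

#' Belief and plausibility of a decision
#'
#' Belief sums the mass of focal sets contained in the decision set A (the
#' environment is never contained in a proper subset); plausibility sums
#' the mass of focal sets intersecting A, which always includes the
#' environment. `[belief, plausibility]` is the evidential interval of A.
#'
#' @param mass a [mass_function()].
#' @param subset character vector of bond keys (the decision set A).
#' @return Numeric scalar.
#' @export
belief_of <- function(mass, subset) {
  subset <- as.character(subset)
  if (length(subset) == 0L) return(0)
  contained <- vapply(mass$focal, function(f) all(f %in% subset), logical(1))
  sum(mass$mass[contained])
}

#' @rdname belief_of
#' @export
plausibility_of <- function(mass, subset) {
  subset <- as.character(subset)
  if (length(subset) == 0L) return(0)
  meets <- vapply(mass$focal, function(f) any(f %in% subset), logical(1))
  sum(mass$mass[meets]) + mass$environment
}
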