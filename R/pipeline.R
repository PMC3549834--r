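#' Fuse per-method evidence into per-bond beliefs
#'
#' The full fusion pipeline for one protein: build the frame of
#' discernment from the methods' reported bonds (union mode by default),
#' convert each method's bond beliefs into a mass function over the
#' consistent focal subsets ([assign_masses()]), combine the mass
#' functions under the requested rule, and extract per-bond containment
#' beliefs ([bond_scores()]).
#'
#' @param evidence_sets list of [evidence_set()] objects (one per
#'   method) for the same protein.
#' @param rule combination rule: `"dempster"`, `"yager"`, `"campos"` or
#'   `"shafer"`.
#' @param weights reliability weights for the Shafer rule (ignored by
#'   the other rules, which consume undiscounted masses); default all 1.
#' @param mode frame mode, see [build_frame()].
#' @param protein required for `"all-pairs"` mode.
#' @param max_card cap on focal subset cardinality.
#' @return List with `scores` (named per-bond beliefs), `result` (the
#'   `combination_result`), `frame`, and `masses` (per-method mass
#'   functions, named by method).
#' @export
fuse_evidence <- function(evidence_sets,
                          rule = c("shafer", "dempster", "yager", "campos"),
                          weights = NULL, mode = "union", protein = NULL,
                          max_card = 4L) {
  rule <- match.arg(rule)
  frame <- build_frame(evidence_sets, mode = mode, protein = protein)
  subsets <- enumerate_consistent_subsets(frame, max_card = max_card)
  masses <- lapply(evidence_sets, function(ev) {
    assign_masses(frame, ev, subsets = subsets)
  })
  names(masses) <- vapply(evidence_sets, `[[`, character(1), "method")
  result <- switch(
    rule,
    dempster = combine_dempster(masses),
    yager = combine_yager(masses),
    campos = combine_campos(masses),
    shafer = {
      if (is.null(weights)) weights <- rep(1, length(masses))
      combine_shafer(masses, weights)
    }
  )
  scores <- bond_scores(result)
  # bonds of the frame that ended with no supporting focal set score 0
  missing <- setdiff(frame$hypotheses, names(scores))
  if (length(missing) > 0L) {
    scores <- c(scores, stats::setNames(rep(0, length(missing)), missing))
    scores <- scores[sort_bonds(names(scores))]
  }
  list(scores = scores, result = result, frame = frame, masses = masses)
}

#' Fused topology for one protein
#'
#' Runs [fuse_evidence()] and reduces the per-bond beliefs to a globally
#' consistent topology by maximum-weight matching, dropping bonds whose
#' fused belief falls below `belief_floor`.
#'
#' @inheritParams fuse_evidence
#' @param belief_floor bonds scoring below this are discarded before
#'   matching (default 0.01: beliefs under one percent are treated as
#'   noise).
#' @return List with `topology` (an `ss_topology`), plus everything
#'   [fuse_evidence()] returns.
#' @export
fuse_topology <- function(evidence_sets, rule = "shafer", weights = NULL,
                          mode = "union", protein = NULL, max_card = 4L,
                          belief_floor = 0.01) {
  fused <- fuse_evidence(evidence_sets, rule = rule, weights = weights,
                         mode = mode, protein = protein, max_card = max_card)
  scores <- fused$scores[fused$scores >= belief_floor]
  fused$topology <- global_topology(scores)
  fused
}
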