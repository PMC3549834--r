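#' Cysteine separation profile of a protein
#'
#' The ordered differences between consecutive cysteine positions.
#' Proteins with similar disulfide bonding patterns tend to share folds,
#' and hence similar separation profiles, which makes the profile a
#' usable signature for topology transfer.
#'
#' @param protein an [ss_protein()] with at least two cysteines.
#' @return Integer vector of length (number of cysteines - 1).
#' @export
compute_profile <- function(protein) {
  cys <- protein$cys_positions
  if (length(cys) < 2L) {
    stop("need at least two cysteines to form a separation profile",
         call. = FALSE)
  }
  diff(cys)
}

#' Divergence between two separation profiles
#'
#' The L1 distance between equal-length profiles. Profiles of different
#' length (different cysteine counts) are incomparable and raise an
#' error; callers treat that as no-match.
#'
#' @param x,y integer vectors from [compute_profile()].
#' @return Non-negative numeric divergence D.
#' @export
divergence <- function(x, y) {
  if (length(x) != length(y)) {
    stop("profiles of unequal length are incomparable", call. = FALSE)
  }
  sum(abs(x - y))
}

#' Belief score from a profile divergence
#'
#' Maps divergence D to a belief in (0, 1] via
#' `(1 + log10(1 + D/10))^-2`: 1 at a perfect match, decaying slowly so
#' that moderately divergent matches retain usable belief.
#'
#' @param d divergence, >= 0.
#' @return Belief in (0, 1].
#' @export
csp_belief <- function(d) {
  if (any(d < 0)) stop("divergence must be >= 0", call. = FALSE)
  (1 + log10(1 + d / 10))^(-2)
}

#' Read a CSP reference database (TSV)
#'
#' Columns: `protein_id`; `cys_positions` (comma-joined 1-based
#' positions); `bonds` (comma-joined ordinal pairs `i-j`, meaning the
#' i-th and j-th cysteines are bonded). Each entry's topology must be a
#' valid matching.
#'
#' @param path path to the TSV file.
#' @return List of reference entries: `protein_id`, `cys_positions`,
#'   `profile`, `ordinal_bonds` (integer matrix, columns i/j).
#' @export
read_reference_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "cys_positions", "bonds")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("reference db lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    cys <- as.integer(strsplit(df$cys_positions[i], ",", fixed = TRUE)[[1L]])
    ob <- bond_positions(strsplit(df$bonds[i], ",", fixed = TRUE)[[1L]])
    if (any(ob > length(cys))) {
      stop("entry ", df$protein_id[i], ": bond ordinal exceeds cysteine count",
           call. = FALSE)
    }
    validate_topology(bond(cys[ob[, 1L]], cys[ob[, 2L]]))  # matching check
    list(protein_id = df$protein_id[i], cys_positions = cys,
         profile = diff(cys), ordinal_bonds = ob)
  })
}

#' Predict disulfide topology by nearest separation profile
#'
#' The query profile is compared against every reference entry with the
#' same profile length; the entry with minimal divergence D wins (ties
#' broken by database order, with the tie count surfaced for
#' discounting). The winner's bonds are transferred by cysteine ordinal
#' (the k-th reference cysteine maps to the k-th query cysteine), each
#' carrying belief [csp_belief()] of D.
#'
#' @param protein an [ss_protein()] with at least two cysteines.
#' @param db reference entries from [read_reference_db()].
#' @return List with `evidence` (an [evidence_set()], method `"CSP"`),
#'   `match` (the winning entry or NULL), `divergence`, `belief`,
#'   `n_best_matches`. When no entry is comparable, `evidence` is empty
#'   and `match` is NULL.
#' @export
predict_topology <- function(protein, db) {
  if (length(db) == 0L) stop("reference database is empty", call. = FALSE)
  prof <- compute_profile(protein)
  comparable <- Filter(function(e) length(e$profile) == length(prof), db)
  if (length(comparable) == 0L) {
    return(list(evidence = evidence_set(protein$id, "CSP"),
                match = NULL, divergence = NA_real_, belief = NA_real_,
                n_best_matches = 0L))
  }
  divs <- vapply(comparable, function(e) divergence(prof, e$profile),
                 numeric(1))
  dmin <- min(divs)
  best_idx <- which(divs == dmin)
  entry <- comparable[[best_idx[1L]]]
  belief <- csp_belief(dmin)
  cys <- protein$cys_positions
  ob <- entry$ordinal_bonds
  bonds <- if (nrow(ob) > 0L) bond(cys[ob[, 1L]], cys[ob[, 2L]])
           else character(0)
  list(
    evidence = evidence_set(protein$id, "CSP", bonds,
                            rep(belief, length(bonds))),
    match = entry, divergence = dmin, belief = belief,
    n_best_matches = length(best_idx)
  )
}
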