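#' Read proteins from a FASTA file
#'
#' Each record becomes an [ss_protein()]; cysteine positions are found by
#' scanning the sequence for 'C'. Sequences with no cysteines are valid and
#' yield an empty position list.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return A named list of `ss_protein` objects (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- ss_protein(ids[i], as.character(seqs[[i]]))
  }
  names(out) <- ids
  out
}

#' Construct an evidence set
#'
#' One method's bond-level output for one protein: a set of
#' (bond, belief) pairs with beliefs in \[0, 1\] and no duplicate bonds.
#'
#' @param protein_id text identifier.
#' @param method source tag (e.g. "MS", "SVM", "CSP").
#' @param bonds character vector of bond keys.
#' @param beliefs numeric vector in \[0, 1\], parallel to `bonds`.
#' @return An object of class `evidence_set` with a data frame field
#'   `items` (columns `bond`, `belief`).
#' @export
evidence_set <- function(protein_id, method, bonds = character(0),
                         beliefs = numeric(0)) {
  bonds <- as.character(bonds)
  beliefs <- as.numeric(beliefs)
  if (length(bonds) != length(beliefs)) {
    stop("bonds and beliefs must have equal length", call. = FALSE)
  }
  if (length(bonds) > 0L) {
    m <- bond_positions(bonds)  # validates keys
    bonds <- bond(m[, 1L], m[, 2L])  # canonicalize
    if (anyDuplicated(bonds)) {
      stop("duplicate bond(s) in evidence set: ",
           paste(unique(bonds[duplicated(bonds)]), collapse = ", "),
           call. = FALSE)
    }
    if (any(beliefs < 0 | beliefs > 1 | is.na(beliefs))) {
      stop("beliefs must lie in [0, 1]", call. = FALSE)
    }
    ord <- order(m[, 1L], m[, 2L])
    bonds <- bonds[ord]
    beliefs <- beliefs[ord]
  }
  structure(
    list(protein_id = as.character(protein_id),
         method = as.character(method),
         items = data.frame(bond = bonds, belief = beliefs,
                            stringsAsFactors = FALSE)),
    class = "evidence_set"
  )
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("<evidence_set> %s / %s: %d bond(s)\n",
              x$protein_id, x$method, nrow(x$items)))
  if (nrow(x$items) > 0L) print(x$items, row.names = FALSE)
  invisible(x)
}

#' Look up the belief a method assigned to a bond
#'
#' @param ev an [evidence_set()].
#' @param bonds character vector of bond keys.
#' @return Numeric vector of beliefs; bonds the method did not report get 0.
#' @export
evidence_belief <- function(ev, bonds) {
  idx <- match(as.character(bonds), ev$items$bond)
  out <- ev$items$belief[idx]
  out[is.na(idx)] <- 0
  out
}

#' Read an evidence table (TSV)
#'
#' The interchange format is tab-separated with a header line and columns
#' `protein_id`, `method`, `cys_a`, `cys_b`, `belief`. Rows are grouped by
#' (protein_id, method) into evidence sets; bond positions are
#' canonicalized so either column order is accepted.
#'
#' @param path path to the TSV file.
#' @return A list of [evidence_set()] objects, named `"protein_id/method"`,
#'   in first-appearance order.
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "method", "cys_a", "cys_b", "belief")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("evidence table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$belief) | df$belief < 0 | df$belief > 1)
  if (length(bad) > 0L) {
    stop("belief outside [0, 1] at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  loop <- which(df$cys_a == df$cys_b)
  if (length(loop) > 0L) {
    stop("cys_a == cys_b at row(s) ", paste(loop, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$protein_id, df$method, sep = "/")
  out <- lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    evidence_set(sub$protein_id[1L], sub$method[1L],
                 bond(sub$cys_a, sub$cys_b), sub$belief)
  })
  names(out) <- unique(key)
  out
}

#' Write evidence sets to a TSV file
#'
#' Inverse of [read_evidence_table()]; beliefs are written at full
#' precision so a write/read round trip is exact.
#'
#' @param evidence a single [evidence_set()] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(evidence, path) {
  if (inherits(evidence, "evidence_set")) evidence <- list(evidence)
  rows <- lapply(evidence, function(ev) {
    if (nrow(ev$items) == 0L) return(NULL)
    m <- bond_positions(ev$items$bond)
    data.frame(protein_id = ev$protein_id, method = ev$method,
               cys_a = m[, 1L], cys_b = m[, 2L],
               belief = ev$items$belief, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(protein_id = character(0), method = character(0),
                     cys_a = integer(0), cys_b = integer(0),
                     belief = numeric(0))
  }
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
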