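#' Canonical disulfide bond hypothesis
#'
#' A bond hypothesis is an unordered pair of 1-based cysteine residue
#' positions, stored canonically with the smaller position first. Bonds are
#' represented throughout the package as character keys of the form
#' `"a-b"` with `a < b`, so they can be used as names and set elements.
#'
#' @param cys_a,cys_b 1-based residue positions of the two cysteines.
#' @return A bond key, e.g. `"14-38"`.
#' @examples
#' bond(38, 14)   # "14-38"
#' @export
bond <- function(cys_a, cys_b) {
  a <- as.integer(cys_a)
  b <- as.integer(cys_b)
  if (any(is.na(a)) || any(is.na(b))) {
    stop("bond positions must be integers", call. = FALSE)
  }
  if (any(a < 1L) || any(b < 1L)) {
    stop("bond positions must be >= 1", call. = FALSE)
  }
  if (any(a == b)) {
    stop("a disulfide bond cannot join a cysteine to itself", call. = FALSE)
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste0(lo, "-", hi)
}

#' Split bond keys back into position pairs
#'
#' @param bonds character vector of bond keys.
#' @return Integer matrix with columns `cys_a`, `cys_b` (one row per bond).
#' @export
bond_positions <- function(bonds) {
  if (length(bonds) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("cys_a", "cys_b"))))
  }
  parts <- strsplit(as.character(bonds), "-", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed bond key(s): ", paste(bonds[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("cys_a", "cys_b")))
  m
}

# numeric-order sort of bond keys (by cys_a, then cys_b); lexicographic
# string order would misplace multi-digit positions
sort_bonds <- function(bonds) {
  if (length(bonds) <= 1L) return(as.character(bonds))
  m <- bond_positions(bonds)
  as.character(bonds)[order(m[, 1L], m[, 2L])]
}

#' Protein record
#'
#' Holds a protein identifier, its amino-acid sequence (1-letter codes) and
#' the 1-based positions of its cysteines. Positions are derived from the
#' sequence and validated against it.
#'
#' @param id text identifier.
#' @param sequence amino-acid string.
#' @return An object of class `ss_protein` with fields `id`, `sequence`,
#'   `cys_positions`.
#' @examples
#' p <- ss_protein("p", "ACCA")
#' p$cys_positions  # 2 3
#' @export
ss_protein <- function(id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence)) {
    stop("sequence must be a single string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  cys <- which(chars == "C")
  structure(
    list(id = as.character(id), sequence = sequence,
         cys_positions = as.integer(cys)),
    class = "ss_protein"
  )
}

#' @export
print.ss_protein <- function(x, ...) {
  cat(sprintf("<ss_protein> %s: %d aa, %d cysteines at [%s]\n",
              x$id, nchar(x$sequence), length(x$cys_positions),
              paste(x$cys_positions, collapse = ", ")))
  invisible(x)
}

#' Validate a set of bonds as a disulfide topology
#'
#' A topology is a set of bonds forming a matching on the cysteines: no two
#' bonds may share a residue position. Bond sets violating this are
#' rejected with an error naming the clashing bonds.
#'
#' @param bonds character vector of bond keys (see [bond()]).
#' @return An object of class `ss_topology` (sorted unique bond keys).
#' @examples
#' validate_topology(c(bond(5, 55), bond(14, 38), bond(31, 51)))
#' @export
validate_topology <- function(bonds) {
  bonds <- unique(as.character(bonds))
  if (length(bonds) > 0L) {
    m <- bond_positions(bonds)
    pos <- c(m[, 1L], m[, 2L])
    dup <- unique(pos[duplicated(pos)])
    if (length(dup) > 0L) {
      clash <- bonds[m[, 1L] %in% dup | m[, 2L] %in% dup]
      stop("bonds share cysteine(s) ", paste(dup, collapse = ", "),
           ": ", paste(sort_bonds(clash), collapse = ", "), call. = FALSE)
    }
  }
  structure(sort_bonds(bonds), class = "ss_topology")
}

#' @export
print.ss_topology <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<ss_topology> empty\n")
  } else {
    cat("<ss_topology>", paste(unclass(x), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Test whether a bond set is a matching
#'
#' Predicate form of [validate_topology()]: `TRUE` when no two bonds share
#' a cysteine position.
#'
#' @param bonds character vector of bond keys.
#' @return Logical scalar.
#' @export
is_consistent <- function(bonds) {
  if (length(bonds) <= 1L) return(TRUE)
  m <- bond_positions(unique(as.character(bonds)))
  pos <- c(m[, 1L], m[, 2L])
  !anyDuplicated(pos)
}

#' All candidate cysteine pairs of a protein
#'
#' @param protein an [ss_protein()].
#' @return Character vector of bond keys for all n(n-1)/2 pairs.
#' @export
all_pairs <- function(protein) {
  cys <- protein$cys_positions
  if (length(cys) < 2L) return(character(0))
  cmb <- utils::combn(cys, 2L)
  bond(cmb[1L, ], cmb[2L, ])
}
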