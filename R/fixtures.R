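#' Path to a packaged data file
#'
#' @param name file name under the package's `extdata` directory; with
#'   no argument, lists the available files.
#' @return A file path (or a character vector of names).
#' @export
ds_fixture_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "dsfusion")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop("no packaged data file '", name, "'; available: ",
         paste(list.files(dir), collapse = ", "), call. = FALSE)
  }
  path
}

#' Packaged study data sets
#'
#' Loaders for the data shipped with the package:
#'
#' * `load_conflict_example()` — two hypothetical methods' evidence for
#'   bovine pancreatic trypsin inhibitor (PDB 1G6X), a textbook case of
#'   highly conflicting sources agreeing only on a low-belief bond.
#' * `load_benchmark_bonds()` — known disulfide linkages of seven
#'   eukaryotic glycosyltransferases and the bonds determined for them
#'   by an MS-based method (MS2DB+), an SVM sequence predictor and a
#'   CSP profile matcher.
#' * `load_case_study()` — the three methods' evidence for
#'   beta-1,4-galactosyltransferase (P08037), the worked fusion example.
#' * `load_fused_bonds()` — bonds and beliefs obtained by fusing the
#'   three methods with the Shafer rule on the benchmark proteins.
#' * `load_massmatrix_bonds()` — bonds from combining the MassMatrix
#'   search engine with the two sequence predictors, per rule family.
#' * `load_csp_refdb()` — a small synthetic CSP reference database (a
#'   stand-in for a curated annotated-topology collection).
#'
#' @return `load_conflict_example` and `load_case_study` return lists of
#'   [evidence_set()]; `load_csp_refdb` returns reference entries (see
#'   [read_reference_db()]); the others return data frames.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
load_conflict_example <- function() {
  read_evidence_table(ds_fixture_path("bpti_conflict_evidence.tsv"))
}

#' @rdname fixtures
#' @export
load_benchmark_bonds <- function() {
  df <- utils::read.delim(ds_fixture_path("glycosyltransferase_bonds.tsv"),
                          stringsAsFactors = FALSE)
  df$bond <- bond(df$cys_a, df$cys_b)
  df
}

#' @rdname fixtures
#' @export
load_case_study <- function() {
  read_evidence_table(ds_fixture_path("b14galt_case_study.tsv"))
}

#' @rdname fixtures
#' @export
load_fused_bonds <- function() {
  df <- utils::read.delim(ds_fixture_path("shafer_fused_bonds.tsv"),
                          stringsAsFactors = FALSE, na.strings = "NA")
  df$bond <- bond(df$cys_a, df$cys_b)
  df
}

#' @rdname fixtures
#' @export
load_massmatrix_bonds <- function() {
  df <- utils::read.delim(ds_fixture_path("massmatrix_fused_bonds.tsv"),
                          stringsAsFactors = FALSE)
  df$bond <- bond(df$cys_a, df$cys_b)
  df
}

#' @rdname fixtures
#' @export
load_csp_refdb <- function() {
  read_reference_db(ds_fixture_path("csp_refdb_synthetic.tsv"))
}
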