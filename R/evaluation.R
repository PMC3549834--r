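#' Confusion counts over a pair universe
#'
#' Counts true/false positives and negatives for a predicted bond set
#' against the known topology, over an explicit universe of candidate
#' pairs (normally all n(n-1)/2 cysteine pairs).
#'
#' @param pred predicted bond keys (a topology or plain vector).
#' @param truth known bond keys.
#' @param universe all candidate bond keys; must contain `truth` and
#'   `pred`.
#' @return List with `tp`, `fp`, `tn`, `fn`, `p` (true bonds),
#'   `n` (true non-bonded pairs).
#' @export
confusion <- function(pred, truth, universe) {
  pred <- unique(as.character(pred))
  truth <- unique(as.character(truth))
  universe <- unique(as.character(universe))
  if (length(setdiff(truth, universe)) > 0L) {
    stop("truth bonds outside the pair universe", call. = FALSE)
  }
  out_pred <- setdiff(pred, universe)
  if (length(out_pred) > 0L) {
    stop("predicted bond(s) outside the pair universe: ",
         paste(out_pred, collapse = ", "), call. = FALSE)
  }
  tp <- length(intersect(pred, truth))
  fp <- length(setdiff(pred, truth))
  fn <- length(setdiff(truth, pred))
  tn <- length(universe) - tp - fp - fn
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       p = length(truth), n = length(universe) - length(truth))
}

#' Detection counts from bond lists alone
#'
#' Sensitivity-family counts when the full cysteine list (and hence the
#' negative-pair universe) is unavailable: true positives, false
#' negatives and false positives from the predicted and known bond sets.
#'
#' @param pred,truth bond key vectors.
#' @return List with `tp`, `fn`, `fp`, `p`.
#' @export
detection_counts <- function(pred, truth) {
  pred <- unique(as.character(pred))
  truth <- unique(as.character(truth))
  list(tp = length(intersect(pred, truth)),
       fn = length(setdiff(truth, pred)),
       fp = length(setdiff(pred, truth)),
       p = length(truth))
}

#' Performance metrics from confusion counts
#'
#' Accuracy Q2 = (TP+TN)/(P+N), sensitivity Qc = TP/P, specificity
#' Qnc = TN/N, and Matthews correlation coefficient with the standard
#' four-factor denominator. A metric whose denominator is zero is
#' undefined and reported as `NA`.
#'
#' @param c confusion counts from [confusion()] (or a compatible list;
#'   `tn`/`n` may be absent, in which case only sensitivity is defined).
#' @return List with `q2`, `qc`, `qnc`, `mcc`.
#' @export
metrics <- function(c) {
  tp <- c$tp; fp <- c$fp
  tn <- if (is.null(c$tn)) NA_integer_ else c$tn
  fn <- c$fn
  p <- if (is.null(c$p)) tp + fn else c$p
  n <- if (is.null(c$n)) NA_integer_ else c$n
  qc <- if (p > 0) tp / p else NA_real_
  qnc <- if (!is.na(n) && n > 0) tn / n else NA_real_
  q2 <- if (!is.na(n) && (p + n) > 0) (tp + tn) / (p + n) else NA_real_
  mcc <- if (!is.na(tn)) {
    den <- sqrt(as.numeric(tp + fn)) * sqrt(as.numeric(tp + fp)) *
           sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
    if (den > 0) (tp * tn - fp * fn) / den else NA_real_
  } else NA_real_
  list(q2 = q2, qc = qc, qnc = qnc, mcc = mcc)
}

#' Macro-average metrics over proteins
#'
#' Arithmetic mean of each metric across proteins, skipping undefined
#' (`NA`) entries. This per-protein averaging is what aggregate
#' performance tables report; pooled (micro) counts are obtained by
#' summing confusion counts before calling [metrics()].
#'
#' @param per_protein list of [metrics()] results.
#' @return A single metric list (`q2`, `qc`, `qnc`, `mcc`).
#' @export
macro_metrics <- function(per_protein) {
  if (length(per_protein) == 0L) stop("no proteins", call. = FALSE)
  avg <- function(field) {
    v <- vapply(per_protein, function(m) as.numeric(m[[field]]), numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  list(q2 = avg("q2"), qc = avg("qc"), qnc = avg("qnc"), mcc = avg("mcc"))
}
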