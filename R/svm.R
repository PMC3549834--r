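# the 20 standard amino acids, fixed order for one-hot encoding
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

#' Local-environment features for a cysteine pair
#'
#' Two 13-residue windows are centered on the two cysteines (6 residues
#' either side of each). Every window position is one-hot encoded over
#' the 20 standard amino acids; positions falling outside the sequence,
#' and non-standard residues (X, U, B, Z, ...), encode as all-zero
#' blocks. The final feature is the raw residue separation d_ss between
#' the two cysteines. Total length: 2 x 13 x 20 + 1 = 521.
#'
#' @param protein an [ss_protein()].
#' @param bond a bond key; both positions must be cysteines of `protein`.
#' @return Numeric vector of length 521 with attribute `d_ss`.
#' @export
encode_pair <- function(protein, bond) {
  pos <- bond_positions(bond)
  a <- unname(pos[1L, 1L]); b <- unname(pos[1L, 2L])
  if (!(a %in% protein$cys_positions) || !(b %in% protein$cys_positions)) {
    stop("bond ", bond, " does not join two cysteines of ", protein$id,
         call. = FALSE)
  }
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1L]]
  window_block <- function(center) {
    block <- numeric(13L * 20L)
    offs <- -6L:6L
    for (w in seq_along(offs)) {
      p <- center + offs[w]
      if (p >= 1L && p <= length(chars)) {
        hit <- match(chars[p], AA20)
        if (!is.na(hit)) block[(w - 1L) * 20L + hit] <- 1
      }
    }
    block
  }
  v <- c(window_block(a), window_block(b), b - a)
  attr(v, "d_ss") <- b - a
  v
}

#' Sigmoid calibration of a classifier margin into a belief
#'
#' Maps a raw decision value f to `1 / (1 + exp(A*f + B))`. With A < 0
#' (the convention used here: positive margins mean "bonded") the belief
#' increases with f, staying strictly inside (0, 1).
#'
#' @param f numeric margin(s).
#' @param params a [platt_params()].
#' @return Numeric belief(s) in (0, 1).
#' @export
platt_belief <- function(f, params) {
  1 / (1 + exp(params$A * f + params$B))
}

#' Calibration parameters
#'
#' @param A,B finite reals; with the package's sign convention A < 0.
#' @return A `platt_params` object.
#' @export
platt_params <- function(A, B) {
  if (!is.finite(A) || !is.finite(B)) {
    stop("A and B must be finite", call. = FALSE)
  }
  structure(list(A = A, B = B), class = "platt_params")
}

#' Fit sigmoid calibration by regularized maximum likelihood
#'
#' Newton's method on the regularized negative log likelihood of
#' `P(y = 1 | f) = 1 / (1 + exp(A*f + B))`, with the label targets
#' softened to (N+ + 1)/(N+ + 2) and 1/(N- + 2) so the fit does not
#' saturate on separable data.
#'
#' @param f numeric vector of decision values.
#' @param y 0/1 (or logical) labels, 1 = bonded.
#' @param max_iter Newton iteration cap.
#' @param tol convergence tolerance on the step size.
#' @return A [platt_params()].
#' @export
fit_platt <- function(f, y, max_iter = 100L, tol = 1e-6) {
  y <- as.integer(y)
  stopifnot(length(f) == length(y), all(y %in% c(0L, 1L)))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y == 1L, hi, lo)
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))          # P(y = 1)
    # gradient of -sum(t*log p + (1-t)*log(1-p)) w.r.t. (A, B);
    # d(-loglik)/dz = p - t is for the logistic 1/(1+e^-z); ours flips sign
    g_z <- t - p
    gA <- sum(g_z * f)
    gB <- sum(g_z)
    w <- p * (1 - p)
    hAA <- sum(w * f * f) + 1e-12
    hAB <- sum(w * f)
    hBB <- sum(w) + 1e-12
    det <- hAA * hBB - hAB * hAB
    dA <- -(hBB * gA - hAB * gB) / det
    dB <- -(hAA * gB - hAB * gA) / det
    A <- A + dA
    B <- B + dB
    if (max(abs(dA), abs(dB)) < tol) break
  }
  platt_params(A, B)
}

#' Train a reference margin-scoring classifier
#'
#' A pluggable classifier for [predict_pairs()] is any function mapping a
#' 521-length feature vector to a real margin (positive = bonded). This
#' helper fits a support vector machine with an RBF kernel on encoded
#' training pairs and returns such a function, with the decision-value
#' sign oriented so positive means bonded.
#'
#' @param features numeric matrix, one encoded pair per row.
#' @param labels 0/1 labels, 1 = bonded.
#' @param cost,gamma SVM hyperparameters passed to [e1071::svm()].
#' @return A function `(feature vector) -> margin`.
#' @export
train_reference_classifier <- function(features, labels, cost = 1,
                                       gamma = 1 / ncol(features)) {
  labels <- factor(as.integer(labels), levels = c(0L, 1L))
  fit <- e1071::svm(features, labels, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  # decision value sign is tied to the order classes were seen; probe it
  dv <- attr(stats::predict(fit, features, decision.values = TRUE),
             "decision.values")[, 1L]
  flip <- if (mean(dv[labels == "1"]) < mean(dv[labels == "0"])) -1 else 1
  function(v) {
    dv <- attr(stats::predict(fit, matrix(v, nrow = 1L),
                              decision.values = TRUE),
               "decision.values")[1L, 1L]
    flip * dv
  }
}

#' Score every cysteine pair of a protein with a classifier
#'
#' Encodes each candidate pair, obtains the classifier margin, calibrates
#' it into a belief with [platt_belief()], and returns the pairs at or
#' above the belief floor as an evidence set.
#'
#' @param protein an [ss_protein()].
#' @param classifier function mapping a 521-length feature vector to a
#'   real margin (see [train_reference_classifier()]).
#' @param params a [platt_params()].
#' @param belief_floor pairs with calibrated belief below this are
#'   omitted (default 0 = keep all).
#' @return An [evidence_set()] with method `"SVM"`; empty for proteins
#'   with fewer than two cysteines.
#' @export
predict_pairs <- function(protein, classifier, params, belief_floor = 0) {
  pairs <- all_pairs(protein)
  if (length(pairs) == 0L) {
    return(evidence_set(protein$id, "SVM"))
  }
  beliefs <- vapply(pairs, function(b) {
    platt_belief(classifier(encode_pair(protein, b)), params)
  }, numeric(1))
  keep <- beliefs >= belief_floor
  evidence_set(protein$id, "SVM", pairs[keep], unname(beliefs[keep]))
}
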