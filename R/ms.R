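# monoisotopic residue masses (Da) and mass constants
RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_PROTON <- 1.007276
MASS_H <- 1.007825
MASS_H2O <- 18.010565
MASS_CO <- 27.994915
MASS_NH3 <- 17.026549

residue_sum <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- RESIDUE_MONO[chars]
  if (anyNA(m)) {
    stop("non-standard residue(s) in '", seq, "'", call. = FALSE)
  }
  sum(m)
}

#' Monoisotopic mass of a peptide
#'
#' @param seq peptide sequence (standard 1-letter codes).
#' @return Neutral monoisotopic mass in Daltons (residues + water).
#' @export
peptide_mass <- function(seq) {
  residue_sum(seq) + MASS_H2O
}

#' Proteolytic digestion
#'
#' Cleaves a protein with trypsin (after K or R, not before P) or
#' chymotrypsin (after F, W or Y, not before P), allowing up to
#' `missed_cleavages` internal missed sites.
#'
#' @param protein an [ss_protein()].
#' @param protease `"trypsin"` or `"chymotrypsin"`.
#' @param missed_cleavages maximum missed cleavage sites per peptide.
#' @return Data frame with columns `seq`, `start`, `end`, `missed`.
#' @export
digest <- function(protein, protease = c("trypsin", "chymotrypsin"),
                   missed_cleavages = 0L) {
  protease <- match.arg(protease)
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  site_res <- if (protease == "trypsin") c("K", "R") else c("F", "W", "Y")
  cut_after <- which(chars %in% site_res)
  cut_after <- cut_after[cut_after < n & chars[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)  # peptide i spans bounds[i]+1 .. bounds[i+1]
  bounds <- unique(bounds)
  k <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(k)) {
    for (j in i:min(i + missed_cleavages, k)) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        seq = paste(chars[s:e], collapse = ""),
        start = s, end = e, missed = j - i, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Enumerate candidate disulfide-bonded peptide pairs
#'
#' All pairs of cysteine-containing peptides from the digest (including a
#' single peptide carrying an intra-peptide bond between two of its own
#' cysteines), one candidate per distinct cysteine pair. The linked mass
#' is the sum of the peptide monoisotopic masses minus two hydrogens
#' (the S-S linkage).
#'
#' @inheritParams digest
#' @return List of candidates: `peptide_a`, `peptide_b` (rows of the
#'   digest table; identical for intra-peptide bonds), `bond` (key),
#'   `mass` (Da), `intra` (logical).
#' @export
enumerate_pairs <- function(protein, protease = "trypsin",
                            missed_cleavages = 0L) {
  peps <- digest(protein, protease, missed_cleavages)
  cys <- protein$cys_positions
  if (length(cys) < 2L) return(list())
  pep_cys <- lapply(seq_len(nrow(peps)), function(i) {
    cys[cys >= peps$start[i] & cys <= peps$end[i]]
  })
  has_cys <- which(lengths(pep_cys) > 0L)
  out <- list()
  add <- function(i, j, ca, cb) {
    pa <- peps[i, , drop = FALSE]
    pb <- peps[j, , drop = FALSE]
    intra <- i == j
    mass <- if (intra) peptide_mass(pa$seq) - 2 * MASS_H
            else peptide_mass(pa$seq) + peptide_mass(pb$seq) - 2 * MASS_H
    out[[length(out) + 1L]] <<- list(
      peptide_a = pa, peptide_b = pb, bond = bond(ca, cb),
      mass = mass, intra = intra)
  }
  for (ii in seq_along(has_cys)) {
    i <- has_cys[ii]
    # intra-peptide bonds
    ci <- pep_cys[[i]]
    if (length(ci) >= 2L) {
      cmb <- utils::combn(ci, 2L)
      for (c2 in seq_len(ncol(cmb))) add(i, i, cmb[1L, c2], cmb[2L, c2])
    }
    # inter-peptide bonds with later peptides that do not overlap
    if (ii < length(has_cys)) {
      for (j in has_cys[(ii + 1L):length(has_cys)]) {
        if (peps$start[j] <= peps$end[i] && peps$end[j] >= peps$start[i]) next
        for (ca in ci) for (cb in pep_cys[[j]]) add(i, j, ca, cb)
      }
    }
  }
  out
}

#' Trim a candidate mass list (subset-sum style)
#'
#' Greedy scan of an ascending mass list that keeps an element only when
#' it exceeds (1 + epsilon) times the last kept element. Every removed
#' mass m then has a kept representative m* with
#' `m / (1 + epsilon) <= m* <= m`, so the trimmed list covers the
#' original to relative accuracy epsilon.
#'
#' @param masses ascending numeric vector of candidate masses.
#' @param epsilon relative trimming parameter, > 0.
#' @return The trimmed ascending subset.
#' @export
trim_search_space <- function(masses, epsilon) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (is.unsorted(masses)) stop("masses must be ascending", call. = FALSE)
  if (length(masses) == 0L) return(masses)
  kept <- masses[1L]
  last <- masses[1L]
  for (m in masses[-1L]) {
    if (m > last * (1 + epsilon)) {
      kept <- c(kept, m)
      last <- m
    }
  }
  kept
}

# singly protonated ion series with neutral losses for one peptide of a
# disulfide pair; fragments retaining the bonded cysteine carry the
# intact partner peptide (minus the two linkage hydrogens)
fragment_series <- function(pep_seq, bonded_cys_offset, partner_neutral) {
  chars <- strsplit(pep_seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 2L) return(NULL)
  res <- cumsum(RESIDUE_MONO[chars])
  rows <- list()
  for (i in seq_len(L - 1L)) {
    # N-terminal fragment = residues 1..i; C-terminal = i+1..L
    n_has <- bonded_cys_offset <= i
    c_has <- !n_has
    n_extra <- if (n_has) partner_neutral - 2 * MASS_H else 0
    c_extra <- if (c_has) partner_neutral - 2 * MASS_H else 0
    b <- res[i] + MASS_PROTON + n_extra
    y <- (res[L] - res[i]) + MASS_H2O + MASS_PROTON + c_extra
    a <- b - MASS_CO
    c_ <- b + MASS_NH3
    x <- y + MASS_CO - 2 * MASS_H
    z <- y - MASS_NH3 + MASS_H
    rows[[i]] <- data.frame(
      ion = c("a", "a_o", "a_star", "b", "b_o", "b_star", "c",
              "x", "y", "y_o", "y_star", "z"),
      mz = c(a, a - MASS_H2O, a - MASS_NH3,
             b, b - MASS_H2O, b - MASS_NH3, c_,
             x, y, y - MASS_H2O, y - MASS_NH3, z),
      pos = i, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Theoretical fragment set of a disulfide-bonded peptide pair
#'
#' Backbone fragments (singly charged, monoisotopic) of each peptide
#' under the expanded ion-type model: a, a-H2O, a-NH3, b, b-H2O, b-NH3,
#' c, x, y, y-H2O, y-NH3 and z. A fragment that retains its peptide's
#' bonded cysteine carries the intact partner peptide attached through
#' the S-S bridge. For an intra-peptide bond, fragments that would sever
#' the ring (containing exactly one of the two cysteines) are not
#' generated.
#'
#' @param pair one candidate from [enumerate_pairs()].
#' @return Data frame with columns `ion`, `mz`, `peptide` ("a"/"b").
#' @export
theoretical_fragments <- function(pair) {
  bp <- bond_positions(pair$bond)
  if (pair$intra) {
    pa <- pair$peptide_a
    chars <- strsplit(pa$seq, "", fixed = TRUE)[[1L]]
    L <- length(chars)
    res <- cumsum(RESIDUE_MONO[chars])
    o1 <- bp[1L, 1L] - pa$start + 1L
    o2 <- bp[1L, 2L] - pa$start + 1L
    rows <- list()
    for (i in seq_len(L - 1L)) {
      inside <- i >= o1 && i < o2   # cleavage severs the ring
      if (inside) next
      nb <- if (i >= o2) -2 * MASS_H else 0   # ring fully N-terminal
      cb <- if (i < o1) -2 * MASS_H else 0    # ring fully C-terminal
      b <- res[i] + MASS_PROTON + nb
      y <- (res[L] - res[i]) + MASS_H2O + MASS_PROTON + cb
      a <- b - MASS_CO
      c_ <- b + MASS_NH3
      x <- y + MASS_CO - 2 * MASS_H
      z <- y - MASS_NH3 + MASS_H
      rows[[length(rows) + 1L]] <- data.frame(
        ion = c("a", "a_o", "a_star", "b", "b_o", "b_star", "c",
                "x", "y", "y_o", "y_star", "z"),
        mz = c(a, a - MASS_H2O, a - MASS_NH3,
               b, b - MASS_H2O, b - MASS_NH3, c_,
               x, y, y - MASS_H2O, y - MASS_NH3, z),
        peptide = "a", stringsAsFactors = FALSE)
    }
    frag <- do.call(rbind, rows)
  } else {
    fa <- fragment_series(pair$peptide_a$seq,
                          bp[1L, 1L] - pair$peptide_a$start + 1L,
                          peptide_mass(pair$peptide_b$seq))
    fb <- fragment_series(pair$peptide_b$seq,
                          bp[1L, 2L] - pair$peptide_b$start + 1L,
                          peptide_mass(pair$peptide_a$seq))
    if (!is.null(fa)) fa$peptide <- "a"
    if (!is.null(fb)) fb$peptide <- "b"
    frag <- rbind(fa[, c("ion", "mz", "peptide")],
                  fb[, c("ion", "mz", "peptide")])
  }
  if (is.null(frag) || nrow(frag) == 0L) {
    return(data.frame(ion = character(0), mz = numeric(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  }
  frag <- frag[frag$mz > 0, , drop = FALSE]
  frag[order(frag$mz), , drop = FALSE]
}

#' Construct a spectrum
#'
#' @param precursor_mass precursor ion mass in Daltons (neutral).
#' @param mz,intensity parallel numeric vectors of peaks.
#' @param precursor_charge integer charge.
#' @return An `ms_spectrum` object; peaks are sorted by m/z.
#' @export
ms_spectrum <- function(precursor_mass, mz, intensity,
                        precursor_charge = 1L) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  ord <- order(mz)
  structure(
    list(precursor_mass = precursor_mass,
         precursor_charge = as.integer(precursor_charge),
         peaks = data.frame(mz = mz[ord], intensity = intensity[ord])),
    class = "ms_spectrum"
  )
}

#' Read spectra from an MGF peak list
#'
#' Parses BEGIN IONS / END IONS blocks with PEPMASS, CHARGE and ion
#' lines. PEPMASS is interpreted as the precursor m/z; the neutral
#' precursor mass is derived using the charge (default 1).
#'
#' @param path path to an MGF file.
#' @return List of [ms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      pepmass <- NA_real_
      charge <- 1L
      mz <- numeric(0)
      int <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("PEPMASS=", "", ln), "\\s+")[[1L]][1L])
        } else if (startsWith(ln, "CHARGE=")) {
          charge <- as.integer(sub("\\+.*$", "", sub("CHARGE=", "", ln)))
        } else if (grepl("^[0-9.]", ln)) {
          parts <- strsplit(ln, "\\s+")[[1L]]
          mz <- c(mz, as.numeric(parts[1L]))
          int <- c(int, as.numeric(parts[2L]))
        }
        i <- i + 1L
      }
      if (is.na(pepmass)) stop("MGF block lacks PEPMASS", call. = FALSE)
      neutral <- pepmass * charge - charge * MASS_PROTON
      out[[length(out) + 1L]] <- ms_spectrum(neutral, mz, int, charge)
    }
    i <- i + 1L
  }
  out
}

#' Write spectra to an MGF peak list
#'
#' @param spectra list of [ms_spectrum()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    z <- sp$precursor_charge
    pepmass <- (sp$precursor_mass + z * MASS_PROTON) / z
    writeLines(c("BEGIN IONS",
                 sprintf("PEPMASS=%.6f", pepmass),
                 sprintf("CHARGE=%d+", z),
                 sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Confirmatory match score of a spectrum against theoretical fragments
#'
#' Peaks below `intensity_floor` of the maximum intensity are discarded.
#' A retained peak is a confirmatory match when some theoretical fragment
#' lies within `tolerance` of it. The score is the intensity-weighted
#' fraction of retained peaks matched, on a 0-100 scale: matched peaks'
#' normalized intensities over all retained peaks' normalized
#' intensities.
#'
#' @param spectrum an [ms_spectrum()].
#' @param theoretical data frame from [theoretical_fragments()].
#' @param tolerance match tolerance in Daltons.
#' @param intensity_floor fraction of the maximum intensity below which
#'   peaks are ignored.
#' @return A `match_report`: list with `vs_score`, `n_match` (matched
#'   theoretical fragments), `n_theoretical`, `n_peaks` (retained),
#'   `matched_intensity`, `precursor_mass`, and the retained-peak
#'   intensity `mu`/`sigma` used downstream by [pp2_score()].
#' @export
match_score_vs <- function(spectrum, theoretical, tolerance = 0.5,
                           intensity_floor = 0.1) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (nrow(theoretical) == 0L) {
    stop("empty theoretical fragment set", call. = FALSE)
  }
  pk <- spectrum$peaks
  if (nrow(pk) == 0L) {
    return(structure(list(vs_score = 0, n_match = 0L,
                          n_theoretical = nrow(theoretical), n_peaks = 0L,
                          matched_intensity = 0,
                          precursor_mass = spectrum$precursor_mass,
                          mu = NA_real_, sigma = NA_real_),
                     class = "match_report"))
  }
  floor_abs <- intensity_floor * max(pk$intensity)
  pk <- pk[pk$intensity >= floor_abs, , drop = FALSE]
  i_n <- pk$intensity / max(pk$intensity)
  # peak -> nearest theoretical fragment distance
  matched_peak <- vapply(pk$mz, function(mz) {
    any(abs(theoretical$mz - mz) <= tolerance)
  }, logical(1))
  n_match <- sum(vapply(theoretical$mz, function(mz) {
    any(abs(pk$mz - mz) <= tolerance)
  }, logical(1)))
  vs <- if (sum(i_n) > 0) 100 * sum(i_n[matched_peak]) / sum(i_n) else 0
  structure(
    list(vs_score = vs, n_match = as.integer(n_match),
         n_theoretical = nrow(theoretical), n_peaks = nrow(pk),
         matched_intensity = sum(pk$intensity[matched_peak]),
         precursor_mass = spectrum$precursor_mass,
         mu = mean(pk$intensity), sigma = stats::sd(pk$intensity)),
    class = "match_report"
  )
}

#' Probability that a product ion matches a theoretical fragment by chance
#'
#' `p2 = 2 * m * VM_TH / r`: `m` theoretical fragments, each claiming a
#' window of width twice the match threshold `VM_TH`, over a spectral
#' detection range `r`. The result is capped just below 1; a
#' non-positive value is an error.
#'
#' @param m number of theoretical fragment ions.
#' @param vm_th confirmatory match threshold in Daltons.
#' @param r spectral (mass) detection range in Daltons.
#' @return Probability in (0, 1).
#' @export
p2_of <- function(m, vm_th, r) {
  p2 <- 2 * m * vm_th / r
  if (!is.finite(p2) || p2 <= 0) {
    stop("p2 must be positive; got ", p2, call. = FALSE)
  }
  min(p2, 1 - 1e-12)
}

#' Significance of the number of confirmatory matches
#'
#' The binomial upper-tail probability of observing at least `n_match`
#' random matches among `n` fragments at per-fragment probability `p2`,
#' on a -log10 scale. Zero matches give pp = 0 (the tail is 1); the
#' score grows with `n_match`.
#'
#' @param n number of theoretical fragments.
#' @param n_match number of confirmed matches, `0 <= n_match <= n`.
#' @param p2 per-fragment random-match probability, in (0, 1).
#' @return Non-negative pp score.
#' @export
pp_score <- function(n, n_match, p2) {
  stopifnot(n_match >= 0, n_match <= n)
  if (p2 <= 0 || p2 >= 1) stop("p2 must lie in (0, 1)", call. = FALSE)
  if (n_match == 0L) return(0)
  log_tail <- stats::pbinom(n_match - 1L, n, p2, lower.tail = FALSE,
                            log.p = TRUE)
  -log_tail / log(10)
}

#' Significance of the matched abundance
#'
#' The Gaussian upper-tail probability that the matched abundance reaches
#' `i_match` under a peak-intensity distribution with mean `mu` and
#' standard deviation `sigma`, on a -log10 scale.
#'
#' @param i_match matched abundance (intensity).
#' @param mu,sigma mean and s.d. of the peak-intensity distribution
#'   (`sigma > 0`).
#' @return Non-negative pp2 score.
#' @export
pp2_score <- function(i_match, mu, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  -stats::pnorm(i_match, mean = mu, sd = sigma, lower.tail = FALSE,
                log.p = TRUE) / log(10)
}

#' Globally consistent topology by maximum-weight matching
#'
#' Selects the set of bonds forming a matching on the cysteines (no
#' shared residue) that maximizes the total score. Solved exactly by
#' branch-and-bound over bonds in canonical order; among equal-weight
#' optima the lexicographically first bond set is returned. Zero-score
#' bonds never enter the matching.
#'
#' @param scores named numeric vector: bond key -> non-negative score.
#' @return An `ss_topology` (see [validate_topology()]).
#' @export
global_topology <- function(scores) {
  if (any(scores < 0)) stop("scores must be >= 0", call. = FALSE)
  scores <- scores[scores > 0]
  if (length(scores) == 0L) return(validate_topology(character(0)))
  bonds <- sort_bonds(names(scores))
  w <- unname(scores[bonds])
  pos <- bond_positions(bonds)
  n <- length(bonds)
  suffix <- rev(cumsum(rev(w)))  # upper bound on remaining weight
  best_total <- -1
  best_set <- integer(0)
  search <- function(i, used, members, total) {
    if (i > n) {
      if (total > best_total + 1e-12) {
        best_total <<- total
        best_set <<- members
      }
      return(invisible())
    }
    if (total + suffix[i] <= best_total + 1e-12) return(invisible())
    a <- pos[i, 1L]; b <- pos[i, 2L]
    if (!(a %in% used) && !(b %in% used)) {
      search(i + 1L, c(used, a, b), c(members, i), total + w[i])
    }
    search(i + 1L, used, members, total)
  }
  search(1L, integer(0), integer(0), 0)
  validate_topology(bonds[best_set])
}

#' Score MS/MS spectra against a protein's candidate disulfide pairs
#'
#' The end-to-end MS evidence pipeline: candidate disulfide-bonded
#' peptide pairs are enumerated from the digest, their mass list trimmed
#' (see [trim_search_space()]), and each spectrum is matched against the
#' candidates whose linked mass lies within `precursor_tol` of its
#' precursor mass. Every candidate-spectrum match is scored
#' ([match_score_vs()], [pp_score()], [pp2_score()]); the best pp per
#' bond becomes its belief (pp scaled by `pp_max` and capped at 1). The
#' global topology is the maximum-weight matching over the raw pp
#' scores: the cap is a reporting convention and would otherwise erase
#' the margin between a true bond and a same-peptide-pair decoy.
#'
#' @param protein an [ss_protein()].
#' @param spectra list of [ms_spectrum()] objects.
#' @param protease,missed_cleavages passed to [enumerate_pairs()].
#' @param tolerance fragment match tolerance (Da).
#' @param precursor_tol precursor mass tolerance (Da).
#' @param epsilon trimming parameter for [trim_search_space()].
#' @param intensity_floor passed to [match_score_vs()].
#' @param pp_max pp value mapped to belief 1.
#' @return List with `evidence` (an [evidence_set()], method `"MS"`),
#'   `reports` (per-bond match reports, each carrying `precursor_mass`
#'   and `pp2` for discounting), and `topology` (the maximum-weight
#'   matching).
#' @export
ms_score_spectra <- function(protein, spectra, protease = "trypsin",
                             missed_cleavages = 0L, tolerance = 0.5,
                             precursor_tol = 1.0, epsilon = 1e-4,
                             intensity_floor = 0.1, pp_max = 100) {
  pairs <- enumerate_pairs(protein, protease, missed_cleavages)
  if (length(pairs) == 0L) {
    return(list(evidence = evidence_set(protein$id, "MS"),
                reports = list(), topology = validate_topology(character(0))))
  }
  masses <- vapply(pairs, `[[`, numeric(1), "mass")
  ord <- order(masses)
  pairs <- pairs[ord]
  masses <- masses[ord]
  kept_mass <- trim_search_space(masses, epsilon)
  keep <- masses %in% kept_mass
  pairs <- pairs[keep]
  masses <- masses[keep]
  best <- list()   # bond -> list(pp, report)
  for (sp in spectra) {
    cand <- which(abs(masses - sp$precursor_mass) <= precursor_tol)
    for (ci in cand) {
      th <- theoretical_fragments(pairs[[ci]])
      if (nrow(th) == 0L) next
      rep_ <- match_score_vs(sp, th, tolerance, intensity_floor)
      r <- max(diff(range(sp$peaks$mz)), 1)
      p2 <- p2_of(rep_$n_theoretical, tolerance, r)
      pp <- pp_score(rep_$n_theoretical, rep_$n_match, p2)
      pp2 <- if (is.finite(rep_$sigma) && rep_$sigma > 0) {
        pp2_score(rep_$matched_intensity, rep_$mu, rep_$sigma)
      } else 0
      b <- pairs[[ci]]$bond
      if (is.null(best[[b]]) || pp > best[[b]]$pp) {
        rep_$pp <- pp
        rep_$pp2 <- pp2
        rep_$bond <- b
        best[[b]] <- list(pp = pp, report = rep_)
      }
    }
  }
  if (length(best) == 0L) {
    return(list(evidence = evidence_set(protein$id, "MS"),
                reports = list(), topology = validate_topology(character(0))))
  }
  bonds <- names(best)
  pp <- vapply(best, `[[`, numeric(1), "pp")
  beliefs <- pmin(pp / pp_max, 1)
  list(
    evidence = evidence_set(protein$id, "MS", bonds, unname(beliefs)),
    reports = lapply(best, `[[`, "report"),
    topology = global_topology(stats::setNames(unname(pp), bonds))
  )
}
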