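#' Simulation configuration for synthetic evidence
#'
#' Defines the conditions the synthetic-evidence generator emulates:
#' proteins with an even number of cysteines carrying a planted
#' perfect-matching topology, and three bond-determination methods whose
#' reported beliefs are noisy views of that truth. Defaults mirror the
#' belief spread seen in real fused-evidence tables: confident true
#' bonds (mean 0.85), weak decoys (mean 0.2), occasional per-method
#' dropout, and decoys that conflict with a true bond by sharing one of
#' its cysteines.
#'
#' @param n_proteins number of proteins to simulate.
#' @param n_cys_range inclusive range of cysteine counts; only even
#'   counts are drawn (a perfect matching needs one).
#' @param true_belief_mean,true_belief_sd normal parameters for planted
#'   bond beliefs (clamped to \[0.01, 0.99\]).
#' @param decoy_belief_mean,decoy_belief_sd same for decoy bonds.
#' @param dropout probability a method fails to report a planted bond.
#' @param conflict_rate probability a method adds, per planted bond, a
#'   decoy sharing a cysteine with it.
#' @param n_methods number of simulated methods.
#' @param seed integer seed; all generation is a pure function of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 20L, n_cys_range = c(4L, 10L),
                       true_belief_mean = 0.85, true_belief_sd = 0.05,
                       decoy_belief_mean = 0.2, decoy_belief_sd = 0.05,
                       dropout = 0.1, conflict_rate = 0.1,
                       n_methods = 3L, seed = 1L) {
  probs <- c(dropout, conflict_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  evens <- seq(n_cys_range[1L], n_cys_range[2L])
  evens <- evens[evens %% 2L == 0L]
  if (length(evens) == 0L) {
    stop("a perfect-matching topology needs an even cysteine count; ",
         "n_cys_range contains none", call. = FALSE)
  }
  structure(
    list(n_proteins = as.integer(n_proteins), n_cys_choices = evens,
         true_belief_mean = true_belief_mean,
         true_belief_sd = true_belief_sd,
         decoy_belief_mean = decoy_belief_mean,
         decoy_belief_sd = decoy_belief_sd,
         dropout = dropout, conflict_rate = conflict_rate,
         n_methods = as.integer(n_methods), seed = as.integer(seed)),
    class = "sim_config"
  )
}

clamp_belief <- function(x) pmin(pmax(x, 0.01), 0.99)

# random sequence with cysteines at spaced positions; a tryptic site is
# placed after every cysteine so each one falls in its own peptide --
# inter-peptide linked pairs are the regime MS/MS scoring can localize
random_protein <- function(id, n_cys) {
  gaps <- sample(6:14, n_cys, replace = TRUE)
  cys_pos <- cumsum(gaps) + 1L
  len <- cys_pos[n_cys] + sample(4:10, 1L)
  chars <- sample(setdiff(AA20, c("C", "P")), len, replace = TRUE)
  chars[cys_pos] <- "C"
  chars[cys_pos + 2L] <- "K"
  ss_protein(id, paste(chars, collapse = ""))
}

random_matching <- function(cys_positions) {
  shuffled <- sample(cys_positions)
  half <- length(shuffled) / 2L
  validate_topology(bond(shuffled[seq_len(half)],
                         shuffled[half + seq_len(half)]))
}

#' Generate synthetic proteins, topologies and per-method evidence
#'
#' Draws random sequences with planted perfect-matching disulfide
#' topologies, then simulates each method's evidence: planted bonds are
#' reported (unless dropped out) with beliefs near the true-bond mean,
#' and conflicting decoys sharing a cysteine with a true bond are added
#' at the configured rate with beliefs near the decoy mean. Identical
#' seeds give identical output.
#'
#' @param sim a [sim_config()].
#' @return List with `proteins` (named list of [ss_protein()]),
#'   `topologies` (named list of `ss_topology`), and `evidence` (named
#'   list, one list of [evidence_set()] per protein).
#' @export
generate <- function(sim = sim_config()) {
  withr::with_seed(sim$seed, {
    proteins <- list()
    topologies <- list()
    evidence <- list()
    for (p in seq_len(sim$n_proteins)) {
      id <- sprintf("SYN%03d", p)
      n_cys <- sample(rep(sim$n_cys_choices, 2L), 1L)
      prot <- random_protein(id, n_cys)
      topo <- random_matching(prot$cys_positions)
      sets <- vector("list", sim$n_methods)
      for (m in seq_len(sim$n_methods)) {
        bonds <- character(0)
        beliefs <- numeric(0)
        for (b in topo) {
          if (stats::runif(1) < sim$dropout) next
          bonds <- c(bonds, b)
          beliefs <- c(beliefs, clamp_belief(stats::rnorm(
            1, sim$true_belief_mean, sim$true_belief_sd)))
        }
        for (b in topo) {
          if (stats::runif(1) < sim$conflict_rate) {
            bp <- bond_positions(b)
            anchor <- sample(c(bp[1L, 1L], bp[1L, 2L]), 1L)
            others <- setdiff(prot$cys_positions, c(bp[1L, 1L], bp[1L, 2L]))
            if (length(others) == 0L) next
            decoy <- bond(anchor, sample(rep(others, 2L), 1L))
            if (decoy %in% bonds) next
            bonds <- c(bonds, decoy)
            beliefs <- c(beliefs, clamp_belief(stats::rnorm(
              1, sim$decoy_belief_mean, sim$decoy_belief_sd)))
          }
        }
        sets[[m]] <- evidence_set(id, sprintf("M%d", m), bonds, beliefs)
      }
      proteins[[id]] <- prot
      topologies[[id]] <- topo
      evidence[[id]] <- sets
    }
    list(proteins = proteins, topologies = topologies, evidence = evidence)
  })
}

#' Synthesize MS/MS spectra from a planted topology
#'
#' For each planted bond, the corresponding disulfide-bonded peptide
#' pair is taken from the tryptic digest and a spectrum is built whose
#' peaks are the pair's theoretical fragment masses, plus optional
#' uniform-random noise peaks. With zero noise, every retained peak of a
#' planted spectrum matches its own candidate, so the match score is
#' 100 by construction.
#'
#' @param protein an [ss_protein()].
#' @param topology an `ss_topology` over the protein's cysteines.
#' @param noise_frac number of noise peaks as a fraction of the
#'   fragment count.
#' @param seed integer seed.
#' @param base_intensity intensity given to fragment peaks.
#' @return List of [ms_spectrum()] objects, one per planted bond, each
#'   with a `bond` attribute.
#' @export
synth_spectra <- function(protein, topology, noise_frac = 0, seed = 1L,
                          base_intensity = 100) {
  pairs <- enumerate_pairs(protein, "trypsin", 0L)
  by_bond <- stats::setNames(pairs, vapply(pairs, `[[`, character(1), "bond"))
  withr::with_seed(seed, {
    lapply(as.character(topology), function(b) {
      pair <- by_bond[[b]]
      if (is.null(pair)) {
        stop("no digest candidate for planted bond ", b, call. = FALSE)
      }
      th <- theoretical_fragments(pair)
      mz <- th$mz
      int <- rep(base_intensity, length(mz))
      n_noise <- round(noise_frac * length(mz))
      if (n_noise > 0L) {
        noise_mz <- stats::runif(n_noise, min(mz), max(mz) + 200)
        noise_int <- stats::runif(n_noise, 0.15 * base_intensity,
                                  base_intensity)
        mz <- c(mz, noise_mz)
        int <- c(int, noise_int)
      }
      sp <- ms_spectrum(pair$mass, mz, int)
      attr(sp, "bond") <- b
      sp
    })
  })
}
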