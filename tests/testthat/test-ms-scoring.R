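test_that("tryptic digestion and pair enumeration find linked peptides", {
  p <- ss_protein("p", "ACKRCK")
  peps <- digest(p, "trypsin")
  expect_setequal(peps$seq, c("ACK", "R", "CK"))
  pairs <- enumerate_pairs(p, "trypsin", 0L)
  expect_length(pairs, 1L)
  expect_equal(pairs[[1]]$bond, "2-5")
  expect_equal(pairs[[1]]$peptide_a$seq, "ACK")
  expect_equal(pairs[[1]]$peptide_b$seq, "CK")
  # linked mass = sum of peptide masses minus two hydrogens
  expect_equal(pairs[[1]]$mass,
               peptide_mass("ACK") + peptide_mass("CK") - 2 * 1.007825,
               tolerance = 1e-9)
  # single cysteine: no candidates
  expect_length(enumerate_pairs(ss_protein("q", "ACKAR")), 0L)
})

test_that("proline suppresses cleavage and missed cleavages extend peptides", {
  p <- ss_protein("p", "ACKPACKACK")
  peps0 <- digest(p, "trypsin", 0L)
  expect_true("ACKPACK" %in% peps0$seq)   # K before P not cleaved
  peps1 <- digest(p, "trypsin", 1L)
  expect_true("ACKPACKACK" %in% peps1$seq)
  chy <- digest(ss_protein("q", "ACFACWAC"), "chymotrypsin")
  expect_setequal(chy$seq, c("ACF", "ACW", "AC"))
})

test_that("intra-peptide bonds are enumerated with ring-aware fragments", {
  p <- ss_protein("p", "ACACAK")
  pairs <- enumerate_pairs(p, "trypsin", 0L)
  expect_length(pairs, 1L)
  expect_true(pairs[[1]]$intra)
  expect_equal(pairs[[1]]$mass, peptide_mass("ACACAK") - 2 * 1.007825,
               tolerance = 1e-9)
  th <- theoretical_fragments(pairs[[1]])
  expect_true(nrow(th) > 0)
  expect_true(all(th$mz > 0))
})

test_that("search-space trimming satisfies the coverage guarantee", {
  expect_equal(trim_search_space(c(100, 100.5, 101, 200), 0.01), c(100, 200))
  x <- sort(stats::runif(50, 100, 5000))
  expect_equal(trim_search_space(x, 1e-12), x)  # epsilon -> 0 keeps all
  expect_error(trim_search_space(x, 0), "epsilon")
  withr::with_seed(55, {
    for (rep in 1:20) {
      masses <- sort(stats::runif(sample(5:40, 1), 100, 4000))
      eps <- stats::runif(1, 1e-4, 0.3)
      kept <- trim_search_space(masses, eps)
      expect_true(all(kept %in% masses))
      removed <- setdiff(masses, kept)
      for (m in removed) {
        # a kept representative below m but within relative epsilon
        expect_true(any(kept >= m / (1 + eps) & kept <= m))
      }
    }
  })
})

test_that("match scoring weighs confirmed peaks by intensity", {
  th <- data.frame(ion = c("b", "b", "y"), mz = c(100, 200, 300),
                   peptide = "a", stringsAsFactors = FALSE)
  sp <- ms_spectrum(1000, c(100.1, 200.2, 500), c(100, 50, 50))
  rep_ <- match_score_vs(sp, th, tolerance = 0.5, intensity_floor = 0.1)
  expect_equal(rep_$vs_score, 75)          # 150 of 200 intensity matched
  expect_equal(rep_$n_match, 2L)
  expect_equal(rep_$n_theoretical, 3L)
  # all peaks matched -> 100; none matched -> 0
  sp_all <- ms_spectrum(1000, c(100, 200, 300), c(10, 20, 30))
  expect_equal(match_score_vs(sp_all, th, 0.5)$vs_score, 100)
  sp_none <- ms_spectrum(1000, c(700, 800), c(10, 20))
  expect_equal(match_score_vs(sp_none, th, 0.5)$vs_score, 0)
  expect_error(match_score_vs(sp, th[0, ], 0.5), "empty theoretical")
  # low-intensity peaks are ignored entirely
  sp_floor <- ms_spectrum(1000, c(100, 700), c(100, 5))
  expect_equal(match_score_vs(sp_floor, th, 0.5)$vs_score, 100)
})

test_that("match-count significance follows the binomial tail", {
  expect_equal(pp_score(10, 0, 0.01), 0)
  expect_equal(pp_score(5, 5, 0.01), 10, tolerance = 1e-9)
  expect_equal(p2_of(10, 0.5, 1000), 0.01, tolerance = 1e-12)
  expect_error(p2_of(0, 0.5, 1000), "positive")
  # monotone in the number of matches
  pps <- vapply(0:20, function(k) pp_score(20, k, 0.05), numeric(1))
  expect_true(all(diff(pps) > 0))
  expect_true(all(pps >= 0))
})

test_that("abundance significance is the Gaussian upper tail", {
  expect_equal(pp2_score(50, 50, 10), -log10(0.5), tolerance = 1e-9)
  expect_equal(pp2_score(-1e6, 0, 1), 0, tolerance = 1e-9)
  i <- seq(-20, 80, by = 5)
  v <- vapply(i, function(x) pp2_score(x, 30, 10), numeric(1))
  expect_true(all(diff(v) > 0))
  expect_error(pp2_score(1, 0, 0), "sigma")
})

test_that("maximum-weight matching is optimal and deterministic", {
  sc <- c("1-2" = 0.9, "3-4" = 0.8, "2-3" = 0.95)
  expect_equal(as.character(global_topology(sc)), c("1-2", "3-4"))
  expect_equal(as.character(global_topology(c("1-2" = 0.5))), "1-2")
  expect_length(global_topology(c("1-2" = 0)), 0L)
  withr::with_seed(66, {
    for (rep in 1:20) {
      cys <- sort(sample(1:16, sample(4:8, 1)))
      pairs <- utils::combn(cys, 2)
      all_b <- bond(pairs[1, ], pairs[2, ])
      k <- sample(3:min(10, length(all_b)), 1)
      sc <- stats::setNames(round(stats::runif(k), 3), sample(all_b, k))
      got <- global_topology(sc)
      want <- oracle_max_matching(sc)
      expect_equal(sum(sc[as.character(got)]), want$weight,
                   tolerance = 1e-9)
      expect_true(is_consistent(as.character(got)))
    }
  })
})

test_that("MGF files round-trip spectra", {
  sp <- list(ms_spectrum(2500.5, c(100.1, 250.7, 900.2), c(10, 55, 30),
                         precursor_charge = 2L),
             ms_spectrum(1200, c(300, 400), c(1, 2)))
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, f)
  back <- read_mgf(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$precursor_mass, 2500.5, tolerance = 1e-4)
  expect_equal(back[[1]]$precursor_charge, 2L)
  expect_equal(back[[1]]$peaks$mz, sp[[1]]$peaks$mz, tolerance = 1e-5)
  expect_equal(back[[2]]$peaks$intensity, c(1, 2), tolerance = 1e-3)
})

test_that("planted topologies are recovered from noise-free spectra", {
  withr::with_seed(77, {
    sim <- sim_config(n_proteins = 3L, n_cys_range = c(4L, 6L), seed = 99L)
    g <- generate(sim)
    for (id in names(g$proteins)) {
      prot <- g$proteins[[id]]
      topo <- g$topologies[[id]]
      spectra <- synth_spectra(prot, topo, noise_frac = 0, seed = 7L)
      res <- ms_score_spectra(prot, spectra)
      expect_setequal(as.character(res$topology), as.character(topo))
      # every planted bond's best report is a perfect match
      for (b in as.character(topo)) {
        expect_equal(res$reports[[b]]$vs_score, 100)
      }
    }
  })
})

test_that("planted bonds outrank decoys in pp under 50% noise peaks", {
  sim <- sim_config(n_proteins = 2L, n_cys_range = c(4L, 6L), seed = 123L)
  g <- generate(sim)
  for (id in names(g$proteins)) {
    prot <- g$proteins[[id]]
    topo <- g$topologies[[id]]
    spectra <- synth_spectra(prot, topo, noise_frac = 0.5, seed = 11L)
    res <- ms_score_spectra(prot, spectra)
    planted <- as.character(topo)
    pp <- vapply(res$reports, `[[`, numeric(1), "pp")
    expect_true(all(planted %in% names(pp)))
    decoy_pp <- pp[setdiff(names(pp), planted)]
    if (length(decoy_pp) > 0) {
      expect_gt(min(pp[planted]), max(decoy_pp))
    }
    expect_setequal(as.character(res$topology), planted)
  }
})
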