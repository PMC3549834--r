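case_study_sets <- function() load_case_study()

test_that("union frame collects every reported bond once", {
  cs <- case_study_sets()
  fr <- build_frame(cs)
  expect_setequal(fr$hypotheses, c("134-176", "247-266", "134-247"))
  one <- build_frame(list(evidence_set("P", "MS", "1-2", 0.5)))
  expect_identical(one$hypotheses, "1-2")
  expect_error(build_frame(list(evidence_set("P", "MS"))), "no bonds")
  expect_error(
    build_frame(list(evidence_set("A", "MS", "1-2", 0.5),
                     evidence_set("B", "MS", "1-2", 0.5))),
    "different proteins")
})

test_that("all-pairs frame enumerates n(n-1)/2 hypotheses", {
  chars <- rep("A", 60)
  chars[c(5, 14, 31, 38, 51, 55)] <- "C"
  prot <- ss_protein("p", paste(chars, collapse = ""))
  fr <- build_frame(list(evidence_set("p", "MS", "5-14", 0.5)),
                    mode = "all-pairs", protein = prot)
  expect_length(fr$hypotheses, 15L)
})

test_that("consistent subsets equal the brute-force power-set filter", {
  cs <- case_study_sets()
  fr <- build_frame(cs)
  subs <- enumerate_consistent_subsets(fr, max_card = 4L)
  expect_length(subs, 4L)  # three singletons and the consistent pair
  got <- lapply(subs, sort)
  want <- oracle_consistent_subsets(fr$hypotheses, 4L)
  expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                  vapply(want, paste, character(1), collapse = "|"))

  # random frames up to 6 hypotheses
  withr::with_seed(42, {
    for (rep in 1:10) {
      cys <- sort(sample(1:12, 6))
      pairs <- utils::combn(cys, 2)
      hyp <- sample(bond(pairs[1, ], pairs[2, ]), 6)
      fr <- build_frame(list(evidence_set("p", "M", hyp,
                                          rep(0.5, length(hyp)))))
      for (mc in c(2L, 4L, 6L)) {
        got <- lapply(enumerate_consistent_subsets(fr, mc), sort)
        want <- oracle_consistent_subsets(fr$hypotheses, mc)
        expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                        vapply(want, paste, character(1), collapse = "|"))
      }
    }
  })
})

test_that("two bonds sharing a cysteine leave only singleton subsets", {
  fr <- build_frame(list(evidence_set("p", "M", c("1-2", "2-3"),
                                      c(0.5, 0.5))))
  subs <- enumerate_consistent_subsets(fr)
  expect_true(all(lengths(subs) == 1L))
})

test_that("subset scoring reproduces the case-study raw and normalized masses", {
  cs <- case_study_sets()
  fr <- build_frame(cs)
  ms <- assign_masses(fr, cs[["P08037/MS"]])
  # raw scores: 0.80 and 0.8225 for the singletons, 0.81125 for the pair;
  # total 2.43375 > 1 so they are sum-normalized and the environment is 0
  expect_equal(unname(ms$mass[["134-176"]]), 0.80 / 2.43375, tolerance = 1e-12)
  expect_equal(unname(ms$mass[["247-266"]]), 0.8225 / 2.43375,
               tolerance = 1e-12)
  expect_equal(unname(ms$mass[["134-176+247-266"]]), 0.81125 / 2.43375,
               tolerance = 1e-12)
  expect_equal(ms$environment, 0)
  expect_equal(round(unname(ms$mass[["134-176+247-266"]]), 2), 0.33)

  svm <- assign_masses(fr, cs[["P08037/SVM"]])
  expect_equal(unname(svm$mass[["134-247"]]), 1.0, tolerance = 1e-12)
  expect_length(svm$mass, 1L)

  # middling beliefs score zero under the assignment function, leaving
  # the CSP source vacuous (all mass on the environment)
  csp <- assign_masses(fr, cs[["P08037/CSP"]])
  expect_length(csp$mass, 0L)
  expect_equal(csp$environment, 1)
})

test_that("singleton raw mass is clamped at zero and monotone above 0.5", {
  fr <- build_frame(list(evidence_set("p", "M", "1-2", 0)))
  m0 <- assign_masses(fr, evidence_set("p", "M", "1-2", 0))
  expect_length(m0$mass, 0L)           # max(-1, 0) = 0
  expect_equal(m0$environment, 1)
  # for sigma > 0.5 the singleton raw score is 2.25*sigma - 1
  sigmas <- seq(0.55, 0.95, by = 0.1)
  raws <- vapply(sigmas, function(s) {
    mm <- assign_masses(build_frame(list(evidence_set("p", "M", "1-2", s))),
                        evidence_set("p", "M", "1-2", s))
    if (length(mm$mass)) unname(mm$mass[[1]]) else 0
  }, numeric(1))
  expect_equal(raws, pmin(2.25 * sigmas - 1, 1), tolerance = 1e-12)
  expect_true(all(diff(raws) > 0))
})

test_that("mass-function constraints survive assignment for random beliefs", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      cys <- sort(sample(1:14, sample(4:8, 1)))
      pairs <- utils::combn(cys, 2)
      all_b <- bond(pairs[1, ], pairs[2, ])
      k <- sample(2:min(5, length(all_b)), 1)
      bonds <- sample(all_b, k)
      ev <- evidence_set("p", "M", bonds, stats::runif(k))
      fr <- build_frame(list(ev))
      m <- assign_masses(fr, ev)
      expect_true(all(m$mass >= 0))
      expect_gte(m$environment, 0)
      expect_equal(sum(m$mass) + m$environment, 1, tolerance = 1e-9)
    }
  })
})

test_that("belief and plausibility bracket every decision", {
  m <- mass_function(list("1-2"), 0.6, environment_mass = 0.4)
  expect_equal(belief_of(m, "1-2"), 0.6)
  expect_equal(plausibility_of(m, "1-2"), 1.0)
  single <- mass_function(list("1-2"), 1)
  expect_equal(belief_of(single, "1-2"), 1)
  expect_equal(plausibility_of(single, "1-2"), 1)
  # quantified: belief never exceeds plausibility
  withr::with_seed(11, {
    for (rep in 1:30) {
      m <- random_mass_function()
      bonds <- unique(unlist(m$focal))
      for (i in 1:5) {
        a <- sample(bonds, sample(seq_along(bonds), 1))
        expect_lte(belief_of(m, a), plausibility_of(m, a) + 1e-12)
      }
    }
  })
})
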