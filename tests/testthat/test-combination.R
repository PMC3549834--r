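# hand-evaluated two-source example used across rules:
# m1 = {A: 0.6, env: 0.4}, m2 = {B: 0.5, env: 0.5} with A, B disjoint
hand_sources <- function() {
  list(mass_function(list("1-2"), 0.6, environment_mass = 0.4),
       mass_function(list("3-4"), 0.5, environment_mass = 0.5))
}

test_that("Dempster matches the hand-evaluated orthogonal sum", {
  r <- combine_dempster(hand_sources())
  expect_equal(r$conflict_mass, 0.30, tolerance = 1e-12)
  expect_equal(unname(r$fused$mass[["1-2"]]), 0.30 / 0.70, tolerance = 1e-12)
  expect_equal(unname(r$fused$mass[["3-4"]]), 0.20 / 0.70, tolerance = 1e-12)
  expect_equal(r$fused$environment, 0.20 / 0.70, tolerance = 1e-12)
  expect_equal(r$conflict_weight, log(1 / 0.7), tolerance = 1e-12)
})

test_that("identical certain sources combine without conflict", {
  m <- mass_function(list("1-2"), 1)
  r <- combine_dempster(list(m, m))
  expect_equal(unname(r$fused$mass[["1-2"]]), 1)
  expect_equal(r$conflict_mass, 0)
  expect_equal(r$conflict_weight, 0)
})

test_that("total conflict is an explicit error for Dempster and Campos", {
  m1 <- mass_function(list("1-2"), 1)
  m2 <- mass_function(list("3-4"), 1)
  expect_error(combine_dempster(list(m1, m2)), "total conflict")
  expect_error(combine_campos(list(m1, m2)), "total conflict")
  # Yager represents it: everything becomes ignorance
  y <- combine_yager(list(m1, m2))
  expect_equal(y$fused$environment, 1)
  expect_length(bond_scores(y), 0L)
})

test_that("Yager matches the hand evaluation and keeps conflict as ignorance", {
  r <- combine_yager(hand_sources())
  expect_equal(unname(r$fused$mass[["1-2"]]), 0.30, tolerance = 1e-12)
  expect_equal(unname(r$fused$mass[["3-4"]]), 0.20, tolerance = 1e-12)
  expect_equal(r$fused$environment, 0.50, tolerance = 1e-12)
})

test_that("Campos de-rates the Dempster sum by the conflict weight", {
  r <- combine_campos(hand_sources())
  w <- 1 + log(1 / 0.7)
  expect_equal(unname(r$fused$mass[["1-2"]]), (0.30 / 0.70) / w,
               tolerance = 1e-12)
  expect_equal(round(unname(r$fused$mass[["1-2"]]), 3), 0.316)
  expect_equal(sum(r$fused$mass) + r$fused$environment, 1, tolerance = 1e-12)
})

test_that("Shafer discounting makes a source vacuous at alpha zero", {
  m1 <- mass_function(list("1-2"), 0.8, environment_mass = 0.2)
  m2 <- mass_function(list("3-4"), 0.9, environment_mass = 0.1)
  r <- combine_shafer(list(m1, m2), weights = c(1, 0))
  expect_equal(unname(r$fused$mass[["1-2"]]), 0.40, tolerance = 1e-12)
  expect_false("3-4" %in% names(r$fused$mass))
  expect_equal(r$fused$environment, 0.60, tolerance = 1e-12)
  expect_error(combine_shafer(list(m1, m2), weights = c(1, 1.2)), "0, 1")
  # all alpha = 1 with identical sources returns that source
  same <- combine_shafer(list(m1, m1))
  expect_equal(unname(same$fused$mass[["1-2"]]), 0.8)
})

test_that("every rule matches the exhaustive tuple-enumeration oracle", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      n_src <- sample(2:3, 1)
      masses <- replicate(n_src, random_mass_function(max_focal = 4L),
                          simplify = FALSE)
      cp <- oracle_cross(masses)
      for (rule in c("dempster", "yager", "campos", "shafer")) {
        if (rule %in% c("dempster", "campos") && cp$conflict > 1 - 1e-9) next
        w <- stats::runif(n_src)
        got <- switch(rule,
          dempster = combine_dempster(masses),
          yager = combine_yager(masses),
          campos = combine_campos(masses),
          shafer = combine_shafer(masses, w))
        want <- oracle_combine(masses, rule,
                               if (rule == "shafer") w else rep(1, n_src))
        expect_mf_equal(got$fused, want, tol = 1e-12)
      }
    }
  })
})

test_that("fused masses always conserve unit belief", {
  withr::with_seed(202, {
    for (rep in 1:250) {
      masses <- replicate(2, random_mass_function(max_focal = 3L),
                          simplify = FALSE)
      total_conflict <- oracle_cross(masses)$conflict > 1 - 1e-9
      for (rule in c("dempster", "yager", "campos", "shafer")) {
        if (rule %in% c("dempster", "campos") && total_conflict) next
        r <- switch(rule,
          dempster = combine_dempster(masses),
          yager = combine_yager(masses),
          campos = combine_campos(masses),
          shafer = combine_shafer(masses))
        expect_equal(sum(r$fused$mass) + r$fused$environment, 1,
                     tolerance = 1e-9)
        expect_true(all(r$fused$mass >= -1e-12))
      }
    }
  })
})

test_that("rules are symmetric in source order", {
  withr::with_seed(303, {
    for (rep in 1:10) {
      masses <- replicate(3, random_mass_function(max_focal = 3L),
                          simplify = FALSE)
      perm <- sample(3)
      if (oracle_cross(masses)$conflict < 1 - 1e-9) {
        expect_mf_equal(combine_dempster(masses)$fused,
                        mf_as_vector(combine_dempster(masses[perm])$fused))
        expect_mf_equal(combine_campos(masses)$fused,
                        mf_as_vector(combine_campos(masses[perm])$fused))
      }
      expect_mf_equal(combine_yager(masses)$fused,
                      mf_as_vector(combine_yager(masses[perm])$fused))
      expect_mf_equal(combine_shafer(masses)$fused,
                      mf_as_vector(combine_shafer(masses[perm])$fused))
    }
  })
})

test_that("pairwise-iterated Dempster equals the n-ary form", {
  withr::with_seed(404, {
    for (rep in 1:10) {
      masses <- replicate(3, random_mass_function(max_focal = 3L),
                          simplify = FALSE)
      if (oracle_cross(masses)$conflict > 1 - 1e-9) next
      pair12 <- try(combine_dempster(masses[1:2]), silent = TRUE)
      if (inherits(pair12, "try-error")) next
      iterated <- combine_dempster(list(pair12$fused, masses[[3]]))
      nary <- combine_dempster(masses)
      expect_mf_equal(iterated$fused, mf_as_vector(nary$fused), tol = 1e-10)
    }
  })
})

test_that("rules coincide on focal sets when there is no conflict", {
  # nested/agreeing sources: no tuple has an empty intersection
  m1 <- mass_function(list("1-2", c("1-2", "3-4")), c(0.5, 0.3),
                      environment_mass = 0.2)
  m2 <- mass_function(list("1-2"), 0.7, environment_mass = 0.3)
  d <- combine_dempster(list(m1, m2))
  y <- combine_yager(list(m1, m2))
  c_ <- combine_campos(list(m1, m2))
  expect_equal(d$conflict_mass, 0)
  expect_mf_equal(y$fused, mf_as_vector(d$fused))
  expect_mf_equal(c_$fused, mf_as_vector(d$fused))
})

test_that("bond scores sum fused mass over containing focal sets", {
  m <- mass_function(list("1-2", c("1-2", "3-4")), c(0.4, 0.2),
                     environment_mass = 0.4)
  r <- new_result <- combine_yager(list(m, mass_function(list(), numeric(0),
                                                         1)))
  sc <- bond_scores(r)
  expect_equal(unname(sc[["1-2"]]), 0.6, tolerance = 1e-12)
  expect_equal(unname(sc[["3-4"]]), 0.2, tolerance = 1e-12)
})
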