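# Independent oracles used by the property tests. These deliberately take
# different algorithmic routes from the package implementation: exhaustive
# tuple enumeration for evidence combination, full power-set filtering for
# focal subsets, and exhaustive matching enumeration for topologies.

oracle_key <- function(bonds) paste(sort(bonds), collapse = "|")

# canonical named vector of a package mass_function, using oracle keys
mf_as_vector <- function(m) {
  v <- stats::setNames(as.numeric(m$mass),
                       vapply(m$focal, oracle_key, character(1)))
  v[[".ENV."]] <- m$environment
  v
}

# exhaustive n-ary tuple enumeration: one element (focal set or the
# environment) per source, product of masses onto the intersection
oracle_cross <- function(masses) {
  sets <- lapply(masses, function(m) c(m$focal, list(.env = NULL)))
  wts <- lapply(masses, function(m) c(as.numeric(m$mass), m$environment))
  grid <- expand.grid(lapply(wts, seq_along))
  out <- list(mass = numeric(0), env = 0, conflict = 0)
  for (r in seq_len(nrow(grid))) {
    p <- 1
    inter <- NULL
    is_universe <- TRUE
    for (s in seq_along(masses)) {
      i <- grid[r, s]
      p <- p * wts[[s]][[i]]
      el <- sets[[s]][[i]]
      if (!is.null(el)) {
        inter <- if (is_universe) el else intersect(inter, el)
        is_universe <- FALSE
      }
    }
    if (p == 0) next
    if (is_universe) {
      out$env <- out$env + p
    } else if (length(inter) == 0L) {
      out$conflict <- out$conflict + p
    } else {
      k <- oracle_key(inter)
      out$mass[k] <- if (k %in% names(out$mass)) out$mass[[k]] + p else p
    }
  }
  out
}

oracle_combine <- function(masses, rule, weights = rep(1, length(masses))) {
  if (rule == "shafer") {
    keys <- unique(unlist(lapply(masses, function(m) {
      vapply(m$focal, oracle_key, character(1))
    })))
    acc <- stats::setNames(rep(0, length(keys)), keys)
    env <- 0
    for (s in seq_along(masses)) {
      m <- masses[[s]]
      a <- weights[s]
      ks <- vapply(m$focal, oracle_key, character(1))
      for (i in seq_along(ks)) acc[ks[i]] <- acc[ks[i]] + a * m$mass[[i]]
      env <- env + 1 - a * (1 - m$environment)
    }
    v <- acc / length(masses)
    v[[".ENV."]] <- env / length(masses)
    return(v)
  }
  cp <- oracle_cross(masses)
  if (rule == "dempster") {
    v <- cp$mass / (1 - cp$conflict)
    v[[".ENV."]] <- cp$env / (1 - cp$conflict)
  } else if (rule == "yager") {
    v <- cp$mass
    v[[".ENV."]] <- cp$env + cp$conflict
  } else if (rule == "campos") {
    w <- 1 + log(1 / (1 - cp$conflict))
    v <- cp$mass / (1 - cp$conflict) / w
    env_d <- cp$env / (1 - cp$conflict) / w
    v[[".ENV."]] <- 1 - sum(v) + env_d  # deficit joins the environment
    # note: implementation folds the de-rated environment into the deficit
    v[[".ENV."]] <- 1 - sum(v[names(v) != ".ENV."])
  }
  v
}

expect_mf_equal <- function(m, expected_vec, tol = 1e-12) {
  got <- mf_as_vector(m)
  keys <- union(names(got), names(expected_vec))
  for (k in keys) {
    g <- if (k %in% names(got)) got[[k]] else 0
    e <- if (k %in% names(expected_vec)) expected_vec[[k]] else 0
    expect_equal(g, e, tolerance = tol, info = paste("focal set", k))
  }
}

# random consistent mass function over cysteines 1..n_cys
random_mass_function <- function(n_cys = 8L, max_focal = 4L) {
  cys <- sort(sample(seq_len(20L), n_cys))
  pairs <- utils::combn(cys, 2L)
  bonds <- dsfusion::bond(pairs[1L, ], pairs[2L, ])
  n_focal <- sample(seq_len(max_focal), 1L)
  focal <- list()
  for (i in seq_len(n_focal)) {
    size <- sample(1:2, 1L)
    cand <- sample(bonds, size)
    if (!dsfusion::is_consistent(cand)) cand <- cand[1L]
    key <- paste(sort(cand), collapse = "|")
    focal[[key]] <- cand
  }
  focal <- unname(focal)
  w <- stats::runif(length(focal))
  env <- stats::runif(1, 0, 0.5)
  w <- w / sum(w) * (1 - env)
  dsfusion::mass_function(focal, w, environment_mass = env)
}

# exhaustive maximum-weight matching over all subsets of edges
oracle_max_matching <- function(scores) {
  bonds <- names(scores)
  n <- length(bonds)
  best_w <- 0
  best <- character(0)
  for (mask in 0:(2^n - 1)) {
    sel <- bonds[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (!dsfusion::is_consistent(sel)) next
    w <- sum(scores[sel])
    if (w > best_w + 1e-12) {
      best_w <- w
      best <- sel
    }
  }
  list(weight = best_w, bonds = sort(best))
}

# full power-set filter for consistent subsets
oracle_consistent_subsets <- function(bonds, max_card) {
  out <- list()
  n <- length(bonds)
  for (mask in seq_len(2^n - 1)) {
    sel <- bonds[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (length(sel) <= max_card && dsfusion::is_consistent(sel)) {
      out[[length(out) + 1L]] <- sort(sel)
    }
  }
  out
}
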