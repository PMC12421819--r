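# Independent oracles used across the suite.
#
# Both oracles deliberately use different data layouts and update
# schedules from the package implementations: the isotopomer oracle keys
# positional patterns by "0"/"1" strings and sweeps metabolites
# Gauss-Seidel style (the solver uses bit-indexed vectors and synchronous
# updates); the LP oracle enumerates basic solutions instead of pivoting.

# ---- brute-force positional-isotopomer fixed point ----

oracle_patterns <- function(n) {
  if (n == 0) return("")
  g <- expand.grid(rep(list(c("0", "1")), n), stringsAsFactors = FALSE)
  apply(g[, rev(seq_len(n)), drop = FALSE], 1, paste, collapse = "")
}

oracle_source_dist <- function(fractions) {
  pats <- oracle_patterns(length(fractions))
  p <- vapply(pats, function(s) {
    bits <- as.integer(strsplit(s, "")[[1]])
    prod(ifelse(bits == 1, fractions, 1 - fractions))
  }, 0)
  names(p) <- pats
  p
}

# scenario keys -> external source metabolites, as in the package
oracle_sources <- function(scenario) {
  key <- c("for" = "for_e", ace = "ace_e", co2 = "co2_e", meoh = "meoh_e")
  src <- list()
  for (s in names(scenario$substrate_labels)) {
    src[[key[[s]]]] <- oracle_source_dist(scenario$substrate_labels[[s]])
  }
  if (!"co2_e" %in% names(src)) src[["co2_e"]] <- oracle_source_dist(0)
  src
}

oracle_simulate <- function(model, v, scenario, tol = 1e-12,
                            max_iter = 50000L) {
  stopifnot(scenario$co2_reassimilation == 0)
  if (inherits(v, "c1_flux")) v <- v$v
  nC <- vapply(model$metabolites, function(m) m$n_carbons, 0L)
  sym <- vapply(model$metabolites, function(m) m$symmetric, TRUE)
  sources <- oracle_sources(scenario)

  dists <- lapply(names(nC)[nC > 0], function(m) {
    if (m %in% names(sources)) return(sources[[m]])
    pats <- oracle_patterns(nC[[m]])
    p <- c(1, numeric(length(pats) - 1)); names(p) <- pats
    p
  })
  names(dists) <- names(nC)[nC > 0]

  # oriented producing reactions per metabolite
  prods <- list()
  for (r in model$reactions) {
    if (is.null(r$atom_map) || abs(v[r$id]) <= 1e-9) next
    map <- r$atom_map
    if (v[r$id] < 0) {
      map <- lapply(map, function(e) list(sub = e$prod, si = e$pi,
                                          prod = e$sub, pi = e$si))
    }
    for (p in unique(vapply(map, function(e) e$prod, ""))) {
      prods[[p]] <- c(prods[[p]], list(list(flux = abs(v[r$id]), map = map)))
    }
  }
  # cytosolic CO2 is pinned to the headspace here (rho = 0): the package
  # applies the same rule, so the oracle treats co2 as a source via T_co2
  targets <- setdiff(names(prods), names(sources))

  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (m in targets) {
      if (m == "co2") next
      pats <- oracle_patterns(nC[[m]])
      acc <- stats::setNames(numeric(length(pats)), pats)
      wsum <- 0
      for (pr in prods[[m]]) {
        entries <- Filter(function(e) e$prod == m, pr$map)
        subs <- unique(vapply(entries, function(e) e$sub, ""))
        combos <- expand.grid(lapply(subs, function(s) names(dists[[s]])),
                              stringsAsFactors = FALSE)
        for (ci in seq_len(nrow(combos))) {
          p <- 1
          for (k in seq_along(subs)) p <- p * dists[[subs[k]]][[combos[ci, k]]]
          if (p == 0) next
          out <- rep("0", nC[[m]])
          for (e in entries) {
            k <- match(e$sub, subs)
            out[e$pi] <- substr(combos[ci, k], e$si, e$si)
          }
          key <- paste(out, collapse = "")
          acc[key] <- acc[key] + pr$flux * p
        }
        wsum <- wsum + pr$flux
      }
      acc <- acc / wsum
      if (sym[[m]]) {
        rev_keys <- vapply(names(acc), function(s)
          paste(rev(strsplit(s, "")[[1]]), collapse = ""), "")
        acc <- (acc + acc[rev_keys]) / 2
        names(acc) <- oracle_patterns(nC[[m]])
      }
      delta <- max(delta, max(abs(acc - dists[[m]])))
      dists[[m]] <- acc
    }
    # co2 pool = headspace under rho = 0
    d_co2 <- dists[["co2_e"]]
    delta <- max(delta, max(abs(d_co2 - dists[["co2"]])))
    dists[["co2"]] <- d_co2
    if (delta < tol) break
  }
  mids <- lapply(names(dists), function(m) {
    counts <- vapply(names(dists[[m]]), function(s)
      sum(strsplit(s, "")[[1]] == "1"), 0)
    vapply(0:nC[[m]], function(k) sum(dists[[m]][counts == k]), 0)
  })
  names(mids) <- names(dists)
  list(dists = dists, mids = mids)
}

# ---- LP vertex-enumeration oracle ----
# Enumerates basic solutions of A x = b with the nonbasic variables pinned
# at a finite bound; returns the optimum over feasible vertices.
oracle_lp <- function(obj, A, b, lower, upper, maximize = FALSE,
                      tol = 1e-8) {
  n <- ncol(A); m <- nrow(A)
  stopifnot(n >= m)
  best <- NULL
  bases <- utils::combn(n, m)
  for (ci in seq_len(ncol(bases))) {
    B <- bases[, ci]
    N <- setdiff(seq_len(n), B)
    AB <- A[, B, drop = FALSE]
    if (abs(det(AB)) < 1e-12) next
    choices <- expand.grid(lapply(N, function(j) {
      v <- c(lower[j], upper[j]); unique(v[is.finite(v)])
    }))
    for (ri in seq_len(max(1, nrow(choices)))) {
      xN <- if (length(N) > 0) as.numeric(choices[ri, ]) else numeric(0)
      rhs <- b - if (length(N) > 0) A[, N, drop = FALSE] %*% xN else 0
      xB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n); x[B] <- xB; x[N] <- xN
      if (any(x < lower - tol) || any(x > upper + tol)) next
      val <- sum(obj * x)
      if (is.null(best) || (maximize && val > best$val) ||
          (!maximize && val < best$val)) {
        best <- list(val = val, x = x)
      }
    }
  }
  best
}

# shared tiny fixtures
reporter_aas <- c("Gly", "Ser", "Ala", "Asp", "Glu")

# rG.F core model with all energy costs zeroed: free exchange of every
# cofactor pool plus no maintenance, leaving carbon stoichiometry as the
# only constraint. Used for the carbon-limited pyruvate cap.
free_cofactors_model <- function(strain = "rG.F") {
  params <- default_cofactor_params()
  params$ngam <- 0; params$gam <- 0
  m <- build_core_model(strain, cofactor_params = params)
  m$reactions$DM_pyr$bounds <- c(0, 1000)
  for (cof in c("atp", "nadh", "nadph", "fadh2")) {
    rid <- paste0("FREE_", cof)
    m$reactions[[rid]] <- reaction(rid, stats::setNames(-1, cof),
                                   reversible = TRUE, bounds = c(-1e6, 1e6))
  }
  m$S <- c1flux:::build_S(m)
  m
}

am_records <- function(lst) {
  lapply(lst, function(x) list(sub = x[[1]], si = as.integer(x[[2]]),
                               prod = x[[3]], pi = as.integer(x[[4]])))
}

corrected_from_raw <- function(raw, fragments = default_fragments()) {
  lapply(stats::setNames(nm = names(raw)), function(a) {
    as.numeric(correct_mid(raw[[a]], build_correction_matrix(fragments[[a]])))
  })
}
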