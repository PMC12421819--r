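# Positional-isotopomer simulation at isotopic steady state.
#
# Each metabolite pool with n carbons carries a probability vector over its
# 2^n positional isotopomers (bit i of the zero-based index = carbon i
# labelled, carbon 1 in the lowest bit). At the fixed point, every
# non-source pool equals the flux-weighted mixture of the isotopomer
# products of its producing reactions; substrate pools are assumed
# independent when a reaction condenses two molecules. Full positional
# enumeration is tractable here (<= 6 carbons per metabolite) and easier to
# verify against a brute-force oracle than an EMU decomposition.

#' Labeling scenario
#'
#' @param substrate_labels named list: substrate id (`"for"`, `"ace"`,
#'   `"co2"`, `"meoh"`) -> per-carbon 13C fraction vector (length = carbon
#'   count of the substrate). E.g. `list(for = 0.99, co2 = 0)` for
#'   13C-formate under unlabelled CO2.
#' @param co2_reassimilation fraction in `[0, 1]` of the assimilated CO2
#'   pool drawn from internally released CO2 instead of the headspace.
#'   Default 0: the CO2-enriched headspace dominates.
#' @return a `c1_scenario`.
#' @export
labeling_scenario <- function(substrate_labels, co2_reassimilation = 0) {
  for (s in names(substrate_labels)) {
    f <- substrate_labels[[s]]
    if (any(f < 0 | f > 1)) stop("label fractions must lie in [0,1]: ", s)
  }
  stopifnot(co2_reassimilation >= 0, co2_reassimilation <= 1)
  structure(list(substrate_labels = substrate_labels,
                 co2_reassimilation = co2_reassimilation),
            class = "c1_scenario")
}

#' Canonical tracer scenarios
#'
#' Mirror the tracer designs used for the engineered strains: mixotrophic
#' cultures on formate + acetate under a CO2-enriched headspace, and
#' formatotrophic cultures on formate alone with either unlabelled or
#' labelled CO2. Tracer purity defaults to 0.99.
#'
#' @param purity 13C fraction of the tracer substrates.
#' @param co2_reassimilation see [labeling_scenario()].
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_mixotrophic_unlabeled <- function() {
  labeling_scenario(list("for" = 0, ace = c(0, 0), co2 = 0))
}

#' @rdname scenarios
#' @export
scenario_mixotrophic_tracer <- function(purity = 0.99, co2_reassimilation = 0) {
  # 13C-formate + 1,2-13C2-acetate + 12CO2 headspace
  labeling_scenario(list("for" = purity, ace = c(purity, purity), co2 = 0),
                    co2_reassimilation)
}

#' @rdname scenarios
#' @export
scenario_formatotrophic_12co2 <- function(purity = 0.99, co2_reassimilation = 0) {
  labeling_scenario(list("for" = purity, co2 = 0), co2_reassimilation)
}

#' @rdname scenarios
#' @export
scenario_formatotrophic_13co2 <- function(purity = 0.99, co2_reassimilation = 0) {
  labeling_scenario(list("for" = purity, co2 = purity), co2_reassimilation)
}

#' Flux-route hypotheses for TCA replenishment
#'
#' The three candidate routes that feed oxaloacetate / the TCA pool:
#' full cyclic TCA turnover, glycine oxidation followed by malate synthase,
#' or anaplerotic carboxylation of pyruvate.
#'
#' @param name one of `"cyclic_TCA"`, `"glyoxylate_malate_synthase"`,
#'   `"anaplerosis"`.
#' @param weights optional named flux overrides (reaction id -> flux) mixed
#'   over the canonical route fluxes, for user-defined mixtures.
#' @return a `c1_hypothesis`.
#' @export
flux_hypothesis <- function(name = c("cyclic_TCA",
                                     "glyoxylate_malate_synthase",
                                     "anaplerosis"),
                            weights = NULL) {
  name <- match.arg(name)
  structure(list(name = name, weights = weights), class = "c1_hypothesis")
}

#' Canonical flux pattern for a hypothesis under a scenario
#'
#' Builds the relative fluxes used by the labelling simulation: the rGlyP
#' backbone (uptake, M1, reverse GCS, GlyA, TdcG) is always active;
#' acetyl-CoA comes from acetate (ACS) when the scenario feeds acetate and
#' from pyruvate (PDH) otherwise; the oxidative branch (GltA, Icd) supplies
#' 2-ketoglutarate; and the hypothesis picks the oxaloacetate-producing
#' route. Only flux ratios at branch points matter for the fixed point.
#'
#' @param model a `c1_model`.
#' @param scenario a `c1_scenario`.
#' @param hypothesis a `c1_hypothesis`.
#' @return named flux vector.
#' @export
hypothesis_fluxes <- function(model, scenario, hypothesis) {
  v <- stats::setNames(numeric(length(model$reactions)),
                       names(model$reactions))
  labs <- names(scenario$substrate_labels)
  mixo <- "ace" %in% labs
  if ("for" %in% labs) v["T_for"] <- 1
  v["T_co2"] <- 1
  if (mixo) v["T_ace"] <- 1
  if ("meoh" %in% labs) v[c("T_meoh", "Mdh", "FaldDH")] <- 1
  v[c("FtfL", "GcvTHP", "GlyA", "TdcG")] <- 1
  # Fdh carries the bulk of formate in the formatotroph; its ratio only
  # matters when internally released CO2 is reassimilated.
  if (!mixo && "for" %in% labs) v["Fdh"] <- 4
  if (mixo) v["ACS"] <- 1 else v["PDH"] <- 1
  v[c("GltA", "Icd")] <- 1
  v <- switch(hypothesis$name,
    anaplerosis = { v["Pyc"] <- 1; if (!mixo) v["PDH"] <- 1; v },
    cyclic_TCA = { v[c("SucAB", "Sdh", "FumC", "MalDH")] <- 1; v },
    glyoxylate_malate_synthase = {
      v[c("ThiO", "GlcB", "MalDH")] <- 1
      if (!mixo) v["PDH"] <- 1
      v
    })
  if (!is.null(hypothesis$weights)) {
    v[names(hypothesis$weights)] <- hypothesis$weights
  }
  v
}

source_distribution <- function(fractions) {
  n <- length(fractions)
  d <- 1
  for (i in seq_len(n)) {
    f <- fractions[i]
    d <- c(d * (1 - f), d * f)  # carbon i in the next-higher bit
  }
  d
}

reverse_bits_index <- function(n) {
  # permutation reversing carbon order for symmetric metabolites
  idx <- 0:(2^n - 1)
  rev_idx <- vapply(idx, function(b) {
    r <- 0L
    for (i in 0:(n - 1)) if (bitwAnd(b, bitwShiftL(1L, i)) != 0) {
      r <- bitwOr(r, bitwShiftL(1L, n - 1L - i))
    }
    r
  }, 0L)
  rev_idx + 1L
}

popcount <- function(x) {
  n <- 0L
  while (any(x > 0)) { n <- n + (x %% 2L); x <- x %/% 2L }
  n
}

mid_from_positional <- function(dist, n_carbons) {
  counts <- popcount(0:(2^n_carbons - 1))
  mid <- vapply(0:n_carbons, function(k) sum(dist[counts == k]), 0)
  names(mid) <- paste0("M", 0:n_carbons)
  mid
}

# orient a reaction's atom map along the direction it actually carries flux
oriented_map <- function(r, flux) {
  if (flux >= 0) return(list(map = r$atom_map, stoich = r$stoichiometry))
  inv <- lapply(r$atom_map, function(e) {
    list(sub = e$prod, si = e$pi, prod = e$sub, pi = e$si)
  })
  list(map = inv, stoich = -r$stoichiometry)
}

# distribution of product `prod` given substrate distributions, for one
# reaction: enumerate joint substrate isotopomers, push labels through the
# atom map
product_distribution <- function(map, prod, dists, nC) {
  entries <- Filter(function(e) e$prod == prod, map)
  subs <- unique(vapply(entries, `[[`, "", "sub"))
  np <- nC[[prod]]
  out <- numeric(2^np)
  sub_sizes <- vapply(subs, function(s) 2^nC[[s]], 0)
  # iterate the cartesian product of substrate isotopomer indices
  idx <- rep(1L, length(subs))
  repeat {
    p <- 1
    for (k in seq_along(subs)) p <- p * dists[[subs[k]]][idx[k]]
    if (p > 0) {
      pat <- 0L
      for (e in entries) {
        k <- match(e$sub, subs)
        bit <- bitwAnd(bitwShiftR(idx[k] - 1L, e$si - 1L), 1L)
        if (bit == 1L) pat <- bitwOr(pat, bitwShiftL(1L, e$pi - 1L))
      }
      out[pat + 1L] <- out[pat + 1L] + p
    }
    k <- 1L
    repeat {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sub_sizes[k]) break
      idx[k] <- 1L; k <- k + 1L
      if (k > length(subs)) break
    }
    if (k > length(subs)) break
  }
  out
}

#' Simulate 13C labelling at isotopic steady state
#'
#' Iterates the positional-isotopomer balance to its fixed point: each
#' non-source metabolite's distribution is the flux-weighted mixture over
#' its producing reactions of the label patterns implied by the curated
#' atom maps. Symmetric metabolites (succinate, fumarate) are averaged
#' with their carbon-reversed distribution. Convergence when the maximum
#' absolute change drops below `tol` (default 1e-10, cap 10000 sweeps).
#'
#' @param model a `c1_model` with atom maps.
#' @param flux a `c1_flux` or named flux vector; only reactions with
#'   nonzero flux propagate label.
#' @param scenario a `c1_scenario`.
#' @param tol convergence tolerance on the positional distributions.
#' @param max_iter sweep cap.
#' @return a `c1_isotopomers`: `dists` (positional distributions), `mids`,
#'   `converged`, `residual`, `iterations`.
#' @export
simulate_labeling <- function(model, flux, scenario, tol = 1e-10,
                              max_iter = 10000L) {
  v <- if (inherits(flux, "c1_flux")) flux$v else flux
  nC <- vapply(model$metabolites, `[[`, 0L, "n_carbons")
  sym <- vapply(model$metabolites, `[[`, TRUE, "symmetric")

  # source pools: external metabolites named by the scenario
  src_key <- c("for" = "for_e", ace = "ace_e", co2 = "co2_e",
               meoh = "meoh_e")
  sources <- list()
  for (s in names(scenario$substrate_labels)) {
    mid_id <- if (s %in% names(src_key)) src_key[[s]] else s
    f <- scenario$substrate_labels[[s]]
    if (length(f) != nC[[mid_id]]) {
      stop("label vector length mismatch for ", s)
    }
    sources[[mid_id]] <- source_distribution(f)
  }
  if (!"co2_e" %in% names(sources)) {
    sources[["co2_e"]] <- source_distribution(0)  # natural headspace, no tracer
  }

  # active mapped reactions, oriented along their flux
  active <- list()
  for (r in model$reactions) {
    if (is.null(r$atom_map)) {
      if (abs(v[r$id]) > 1e-9) {
        carbons <- names(r$stoichiometry)[nC[names(r$stoichiometry)] > 0]
        prods <- carbons[r$stoichiometry[carbons] * sign(v[r$id]) > 0]
        if (length(prods) > 0 && any(!prods %in% names(sources))) {
          # lumped drains (biomass, gluconeogenesis) only consume from the
          # labelling subnetwork; a producer without a map is an error
          if (any(prods %in% c("gly", "ser", "pyr", "accoa", "oaa", "akg",
                               "glx", "mal", "succ", "fum", "icit",
                               "methf", "for", "co2"))) {
            stop("flux-carrying reaction without atom map produces ",
                 paste(prods, collapse = ","), ": ", r$id)
          }
        }
      }
      next
    }
    if (abs(v[r$id]) <= 1e-9) next
    om <- oriented_map(r, v[r$id])
    active[[length(active) + 1L]] <- list(id = r$id, flux = abs(v[r$id]),
                                          map = om$map, stoich = om$stoich)
  }

  # producers per metabolite
  producers <- list()
  for (a in active) {
    prods <- unique(vapply(a$map, `[[`, "", "prod"))
    for (p in prods) producers[[p]] <- c(producers[[p]], list(a))
  }

  # initial state: everything unlabelled
  dists <- lapply(names(nC)[nC > 0], function(m) {
    if (m %in% names(sources)) sources[[m]] else
      c(1, numeric(2^nC[[m]] - 1))
  })
  names(dists) <- names(nC)[nC > 0]

  rho <- scenario$co2_reassimilation
  co2_emitters <- Filter(function(a) {
    a$id != "T_co2" && any(vapply(a$map, `[[`, "", "prod") == "co2")
  }, active)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta <- 0
    new <- dists
    for (m in names(producers)) {
      if (m %in% names(sources)) next
      if (m == "co2") next  # handled below
      ps <- producers[[m]]
      w <- vapply(ps, `[[`, 0, "flux")
      acc <- numeric(2^nC[[m]])
      for (k in seq_along(ps)) {
        acc <- acc + w[k] * product_distribution(ps[[k]]$map, m, dists, nC)
      }
      acc <- acc / sum(w)
      if (sym[[m]]) {
        acc <- (acc + acc[reverse_bits_index(nC[[m]])]) / 2
      }
      new[[m]] <- acc
    }
    # assimilated CO2: headspace mixed with internally released CO2
    head_dist <- product_distribution(
      list(list(sub = "co2_e", si = 1L, prod = "co2", pi = 1L)),
      "co2", dists, nC)
    if (rho > 0 && length(co2_emitters) > 0) {
      wsum <- 0; e <- 0
      for (a in co2_emitters) {
        d <- product_distribution(a$map, "co2", dists, nC)
        e <- e + a$flux * d[2]
        wsum <- wsum + a$flux
      }
      e <- e / wsum
      new[["co2"]] <- (1 - rho) * head_dist + rho * c(1 - e, e)
    } else {
      new[["co2"]] <- head_dist
    }
    for (m in names(new)) delta <- max(delta, max(abs(new[[m]] - dists[[m]])))
    dists <- new
    if (delta < tol) break
    if (iter >= max_iter) {
      warning("isotopomer fixed point not converged; residual ", delta)
      break
    }
  }

  mids <- lapply(names(dists), function(m) mid_from_positional(dists[[m]], nC[[m]]))
  names(mids) <- names(dists)
  structure(list(dists = dists, mids = mids, converged = delta < tol,
                 residual = delta, iterations = iter),
            class = "c1_isotopomers")
}

# reporter amino acids inherit their keto-acid precursor skeleton 1:1
aa_precursors <- function() {
  c(Gly = "gly", Ser = "ser", Ala = "pyr", Asp = "oaa", Glu = "akg")
}

#' Mass-isotopomer distribution of a reporter amino acid
#' @param state a `c1_isotopomers`.
#' @param amino_acid `"Gly"`, `"Ser"`, `"Ala"`, `"Asp"` or `"Glu"` (or a
#'   metabolite id).
#' @return numeric MID (`M0`..`Mn`).
#' @export
amino_acid_mid <- function(state, amino_acid) {
  prec <- aa_precursors()
  m <- if (amino_acid %in% names(prec)) prec[[amino_acid]] else amino_acid
  if (!m %in% names(state$mids)) stop("metabolite absent: ", amino_acid)
  state$mids[[m]]
}

#' Dominant isotopomer label count
#'
#' @param state a `c1_isotopomers`.
#' @param metabolite metabolite id or reporter amino-acid name.
#' @return integer label count (argmax of the MID; ties broken toward the
#'   lower count, with a `"tie"` attribute set).
#' @export
dominant_isotopomer <- function(state, metabolite) {
  mid <- amino_acid_mid(state, metabolite)
  mx <- max(mid)
  winners <- which(mid >= mx - 1e-12) - 1L
  out <- as.integer(min(winners))
  attr(out, "tie") <- length(winners) > 1L
  out
}

#' Predicted amino-acid fingerprints per flux hypothesis
#'
#' @param model a `c1_model`.
#' @param scenario a `c1_scenario`.
#' @param hypotheses list of `c1_hypothesis` (default: all three routes).
#' @return named list: hypothesis name -> named list of reporter MIDs
#'   (`Gly`, `Ser`, `Ala`, `Asp`, `Glu`).
#' @export
predict_fingerprints <- function(model, scenario, hypotheses = NULL) {
  if (is.null(hypotheses)) {
    hypotheses <- lapply(c("cyclic_TCA", "glyoxylate_malate_synthase",
                           "anaplerosis"), flux_hypothesis)
  }
  out <- list()
  for (h in hypotheses) {
    v <- hypothesis_fluxes(model, scenario, h)
    st <- simulate_labeling(model, v, scenario)
    out[[h$name]] <- lapply(stats::setNames(nm = names(aa_precursors())),
                            function(a) amino_acid_mid(st, a))
  }
  out
}

#' Score observed MIDs against hypothesis fingerprints
#'
#' Sum of squared MID differences across the reporter amino acids, ranked
#' ascending; the best hypothesis and its margin over the runner-up are
#' returned.
#'
#' @param observed named list: amino acid -> MID (normalised).
#' @param predicted output of [predict_fingerprints()].
#' @return list with `scores` (data.frame, ranked), `best`, `margin`,
#'   `tie`.
#' @export
discriminate_hypotheses <- function(observed, predicted) {
  scores <- vapply(predicted, function(fp) {
    s <- 0
    for (a in names(observed)) {
      if (!a %in% names(fp)) stop("hypothesis fingerprint lacks ", a)
      if (length(observed[[a]]) != length(fp[[a]])) {
        stop("MID length mismatch for ", a)
      }
      s <- s + sum((observed[[a]] - fp[[a]])^2)
    }
    s
  }, 0)
  ord <- order(scores)
  df <- data.frame(hypothesis = names(scores)[ord],
                   score = unname(scores)[ord],
                   stringsAsFactors = FALSE)
  margin <- if (nrow(df) > 1) df$score[2] - df$score[1] else Inf
  list(scores = df, best = df$hypothesis[1], margin = margin,
       tie = margin < 1e-12)
}

#' Write MIDs as CSV (metabolite, M+0..M+n)
#' @param mids named list of MID vectors.
#' @param path output path.
#' @export
mids_to_csv <- function(mids, path) {
  nmax <- max(vapply(mids, length, 0L)) - 1L
  rows <- lapply(names(mids), function(m) {
    v <- mids[[m]]
    c(list(metabolite = m),
      as.list(stats::setNames(c(v, rep(NA, nmax + 1L - length(v))),
                              paste0("M", 0:nmax))))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
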