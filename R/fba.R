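# Flux balance analysis on c1_model objects.
#
# Conventions: exchange reactions are uptake-positive (EX_for = 1 means
# 1 mmol gCDW^-1 h^-1 of formate enters the cell); S v = 0 is enforced for
# every metabolite row. Reversible reactions are split into forward and
# backward non-negative variables inside the solver. Alternate optima are
# resolved for reporting by a parsimonious second pass that minimises
# total |v| at the fixed optimal objective, which makes flux maps
# deterministic.

#' Flux constraint set
#'
#' @param substrate_uptakes named list/vector: substrate id ("for", "ace",
#'   "meoh", or the exchange reaction id) -> either a single value (uptake
#'   fixed at that rate) or `c(lb, ub)` bounds, in mmol gCDW^-1 h^-1.
#' @param gas_phase optional `c(lb, ub)` for the CO2 exchange (default
#'   unconstrained in both directions: CO2-enriched headspace).
#' @param maintenance optional override of the non-growth ATP maintenance
#'   flux (mmol gCDW^-1 h^-1).
#' @return a `c1_constraints` list.
#' @export
flux_constraints <- function(substrate_uptakes = list(), gas_phase = NULL,
                             maintenance = NULL) {
  for (v in substrate_uptakes) {
    if (!all(is.finite(unlist(v)))) stop("uptake rates must be finite")
  }
  structure(list(substrate_uptakes = substrate_uptakes,
                 gas_phase = gas_phase, maintenance = maintenance),
            class = "c1_constraints")
}

uptake_reaction_id <- function(model, substrate) {
  if (substrate %in% names(model$reactions)) return(substrate)
  cand <- paste0("EX_", substrate)
  if (cand %in% names(model$reactions)) return(cand)
  stop("substrate not exchangeable: ", substrate)
}

apply_constraints <- function(model, constraints) {
  lb <- vapply(model$reactions, function(r) r$bounds[1], 0)
  ub <- vapply(model$reactions, function(r) r$bounds[2], 0)
  if (!is.null(constraints)) {
    for (s in names(constraints$substrate_uptakes)) {
      rid <- uptake_reaction_id(model, s)
      v <- unlist(constraints$substrate_uptakes[[s]])
      if (all(model$reactions[[rid]]$bounds == 0) && s != rid) {
        # knocked-out module uptake stays closed
      }
      if (length(v) == 1) v <- c(v, v)
      lb[rid] <- v[1]; ub[rid] <- v[2]
    }
    if (!is.null(constraints$gas_phase)) {
      lb["EX_co2"] <- constraints$gas_phase[1]
      ub["EX_co2"] <- constraints$gas_phase[2]
    }
    if (!is.null(constraints$maintenance)) {
      lb["NGAM"] <- constraints$maintenance
      ub["NGAM"] <- constraints$maintenance
    }
  }
  list(lb = lb, ub = ub)
}

# split reversible reactions into non-negative forward/backward columns
split_problem <- function(model, lb, ub) {
  rids <- names(model$reactions)
  S <- model$S
  cols <- list(); dirs <- list(); owner <- list()
  for (rid in rids) {
    l <- lb[rid]; u <- ub[rid]
    if (l >= 0) {
      cols[[length(cols) + 1L]] <- list(rid = rid, sign = 1, lb = l, ub = u)
    } else if (u <= 0) {
      cols[[length(cols) + 1L]] <- list(rid = rid, sign = -1, lb = -u, ub = -l)
    } else {
      cols[[length(cols) + 1L]] <- list(rid = rid, sign = 1, lb = 0, ub = u)
      cols[[length(cols) + 1L]] <- list(rid = rid, sign = -1, lb = 0, ub = -l)
    }
  }
  A <- do.call(cbind, lapply(cols, function(cl) cl$sign * S[, cl$rid]))
  list(cols = cols, A = A,
       lower = vapply(cols, `[[`, 0, "lb"),
       upper = vapply(cols, `[[`, 0, "ub"))
}

recombine <- function(cols, x, rids) {
  v <- stats::setNames(numeric(length(rids)), rids)
  for (k in seq_along(cols)) v[cols[[k]]$rid] <- v[cols[[k]]$rid] + cols[[k]]$sign * x[k]
  v
}

#' Solve a flux balance problem
#'
#' Maximises the objective reaction flux subject to `S v = 0` and bounds,
#' then (optionally) resolves degenerate alternate optima by minimising
#' total absolute flux at the fixed optimum (parsimonious FBA).
#'
#' @param model a `c1_model`.
#' @param constraints a `c1_constraints` (or `NULL` for the model bounds).
#' @param objective objective reaction id (default the biomass reaction).
#' @param parsimonious run the secondary |v|-minimising LP (default TRUE).
#' @return a `c1_flux` list: `v` (named flux vector), `mu` (objective
#'   value), `status`, `normalized` (filled by [normalize_fluxes()]).
#' @export
solve_fba <- function(model, constraints = NULL, objective = NULL,
                      parsimonious = TRUE) {
  if (is.null(objective)) objective <- model$biomass_reaction_id
  if (!objective %in% names(model$reactions)) {
    stop("objective reaction not in model: ", objective)
  }
  bb <- apply_constraints(model, constraints)
  sp <- split_problem(model, bb$lb, bb$ub)
  nmet <- nrow(sp$A)
  obj <- vapply(sp$cols, function(cl) {
    if (cl$rid == objective) cl$sign else 0
  }, 0)
  res <- solve_lp(obj, sp$A, rep(0, nmet), sp$lower, sp$upper,
                  maximize = TRUE)
  if (res$status != "optimal") {
    return(structure(list(v = stats::setNames(numeric(0), character(0)),
                          mu = NA_real_, status = res$status,
                          normalized = NULL, objective = objective),
                     class = "c1_flux"))
  }
  x <- res$x
  if (parsimonious) {
    # fix objective at optimum, minimise sum of split fluxes
    A2 <- rbind(sp$A, obj)
    b2 <- c(rep(0, nmet), res$objval)
    res2 <- solve_lp(rep(1, length(obj)), A2, b2, sp$lower, sp$upper,
                     maximize = FALSE)
    if (res2$status == "optimal") x <- res2$x
  }
  v <- recombine(sp$cols, x, names(model$reactions))
  resid <- max(abs(model$S %*% v))
  if (resid > 1e-6) stop("mass balance violated at optimum; residual ", resid)
  structure(list(v = v, mu = res$objval, status = "optimal",
                 normalized = NULL, objective = objective),
            class = "c1_flux")
}

#' @export
print.c1_flux <- function(x, ...) {
  cat("c1flux FBA solution: status=", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective (", x$objective, ") = ", signif(x$mu, 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Theoretical biomass yield on a substrate
#'
#' Fixes substrate uptake at `q_s`, maximises growth and returns
#' `mu_max / q_s * 1000` in gCDW per mol of substrate (the model's biomass
#' flux convention is 1 gCDW per unit flux per hour).
#'
#' @param model a `c1_model`.
#' @param substrate substrate id (e.g. `"for"`, `"meoh"`).
#' @param q_s fixed specific uptake rate (mmol gCDW^-1 h^-1); must be > 0.
#' @param constraints optional extra `c1_constraints` merged with the fixed
#'   uptake.
#' @return yield in gCDW mol^-1.
#' @export
theoretical_yield <- function(model, substrate, q_s = 10, constraints = NULL) {
  if (q_s <= 0) stop("substrate uptake must be positive for a yield")
  uptakes <- list(); uptakes[[substrate]] <- q_s
  if (is.null(constraints)) {
    constraints <- flux_constraints(uptakes)
  } else {
    constraints$substrate_uptakes[[substrate]] <- q_s
  }
  fd <- solve_fba(model, constraints, parsimonious = FALSE)
  if (fd$status != "optimal") {
    stop("yield undefined: FBA status ", fd$status)
  }
  fd$mu / q_s * 1000
}

#' Normalise fluxes to substrate uptake = 100
#'
#' @param fd a `c1_flux` from [solve_fba()].
#' @param model the model the fluxes belong to.
#' @param substrate substrate id whose uptake defines 100%.
#' @return the `c1_flux` with `normalized` filled (percentages).
#' @export
normalize_fluxes <- function(fd, model, substrate) {
  rid <- uptake_reaction_id(model, substrate)
  if (fd$status != "optimal") stop("cannot normalise a non-optimal solution")
  q <- fd$v[rid]
  if (!is.finite(q) || q <= 0) stop("zero uptake: cannot normalise")
  fd$normalized <- fd$v / q * 100
  fd$normalized_to <- rid
  fd
}

#' Write a flux map as TSV
#' @param fd a `c1_flux` (run [normalize_fluxes()] first for percentages).
#' @param path output path.
#' @export
flux_map_tsv <- function(fd, path) {
  df <- data.frame(reaction = names(fd$v),
                   flux = signif(unname(fd$v), 3),
                   stringsAsFactors = FALSE)
  if (!is.null(fd$normalized)) {
    df$percent_of_uptake <- signif(unname(fd$normalized), 3)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
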