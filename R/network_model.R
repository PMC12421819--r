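# Core P. putida central-metabolism network extended with the reductive
# glycine pathway (rGlyP) modules and C1-oxidation reactions.
#
# Carbon indexing is 1-based throughout. Conventions fixed here and relied
# on by the isotope simulator:
#   * oxaloacetate C1-C4 with the pyruvate-carboxylase CO2 entering at C4;
#   * acetate C1 (carboxyl) and C2 (methyl) map onto acetyl-CoA C1, C2;
#   * pyruvate C1-C3 inherit serine C1-C3 (deamination);
#   * glycine C1 = carboxyl (from CO2 via the reverse GCS), C2 = alpha
#     carbon (from methylene-THF);
#   * citrate/isocitrate carbons are ordered [OAA C1..C4, AcCoA C1, C2].

#' Create a metabolite record
#'
#' @param id short unique identifier.
#' @param name human-readable name.
#' @param n_carbons non-negative carbon count.
#' @param compartment `"cytosol"` or `"external"`.
#' @param symmetric `TRUE` for rotationally symmetric molecules
#'   (succinate, fumarate), which scramble carbon positions.
#' @return a `c1_metabolite` list.
#' @export
metabolite <- function(id, name = id, n_carbons = 0L,
                       compartment = c("cytosol", "external"),
                       symmetric = FALSE) {
  compartment <- match.arg(compartment)
  n_carbons <- as.integer(n_carbons)
  stopifnot(n_carbons >= 0L)
  if (symmetric && n_carbons < 2L) {
    stop("symmetric metabolites need at least 2 carbons: ", id)
  }
  structure(list(id = id, name = name, n_carbons = n_carbons,
                 compartment = compartment, symmetric = symmetric),
            class = "c1_metabolite")
}

#' Create a reaction record
#'
#' @param id short unique identifier.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (substrates negative).
#' @param reversible logical.
#' @param bounds length-2 numeric flux bounds (mmol gCDW^-1 h^-1).
#' @param atom_map optional list of records `list(sub=, si=, prod=, pi=)`
#'   mapping substrate carbon `si` (1-based) to product carbon `pi`.
#' @param enzyme_label field name of the catalysing enzyme (e.g. "FtfL",
#'   "GcvTHP", "AceA"); used to address knockouts.
#' @return a `c1_reaction` list.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     bounds = NULL, atom_map = NULL, enzyme_label = id) {
  if (is.null(bounds)) bounds <- if (reversible) c(-1000, 1000) else c(0, 1000)
  stopifnot(length(bounds) == 2, bounds[1] <= bounds[2])
  if (!reversible && bounds[1] < 0) {
    stop("irreversible reaction with negative lower bound: ", id)
  }
  structure(list(id = id, stoichiometry = stoichiometry,
                 reversible = reversible, bounds = as.numeric(bounds),
                 atom_map = atom_map, enzyme_label = enzyme_label),
            class = "c1_reaction")
}

am <- function(...) {
  # atom_map helper: am("pyr",1,"co2",1, "pyr",2,"accoa",1, ...)
  v <- list(...)
  stopifnot(length(v) %% 4 == 0)
  lapply(seq_len(length(v) / 4), function(k) {
    i <- (k - 1) * 4
    list(sub = v[[i + 1]], si = as.integer(v[[i + 2]]),
         prod = v[[i + 3]], pi = as.integer(v[[i + 4]]))
  })
}

#' Default cofactor and energy parameters of the core model
#'
#' These are documented defaults, not measured values: P/O ratios of 1.5
#' (NADH) and 1.0 (FADH2) for aerobic P. putida respiration, a
#' growth-associated ATP requirement of 40 mmol ATP gCDW^-1 and a
#' non-growth maintenance of 0.92 mmol ATP gCDW^-1 h^-1.
#'
#' @return named list with `po_nadh`, `po_fadh2`, `gam`, `ngam`.
#' @export
default_cofactor_params <- function() {
  list(po_nadh = 1.5,   # ATP per NADH oxidised
       po_fadh2 = 1.0,  # ATP per FADH2 oxidised
       gam = 40,        # mmol ATP per gCDW (growth-associated)
       ngam = 0.92)     # mmol ATP gCDW^-1 h^-1 (non-growth)
}

# Biomass precursor drain coefficients (mmol per gCDW), a documented
# default compiled from standard precursor-demand tables; not taken from
# any single measured composition. Upper-metabolism precursors (sugar
# phosphates, 3PG/PEP family) are lumped into 3-carbon units ("upper3")
# made from pyruvate by the lumped gluconeogenesis reaction.
biomass_coefficients <- function() {
  c(upper3 = 4.67, pyr = 2.833, accoa = 3.748, oaa = 1.787, akg = 1.079,
    gly = 0.582, ser = 0.205, methf = 0.49, nadph = 18.2)
}

core_metabolites <- function() {
  mets <- list(
    metabolite("for_e", "formate (external)", 1, "external"),
    metabolite("co2_e", "CO2 (external)", 1, "external"),
    metabolite("ace_e", "acetate (external)", 2, "external"),
    metabolite("meoh_e", "methanol (external)", 1, "external"),
    metabolite("for", "formate", 1),
    metabolite("co2", "CO2", 1),
    metabolite("ace", "acetate", 2),
    metabolite("meoh", "methanol", 1),
    metabolite("fald", "formaldehyde", 1),
    metabolite("methf", "5,10-methylene-THF (C1 unit)", 1),
    metabolite("gly", "glycine", 2),
    metabolite("ser", "serine", 3),
    metabolite("pyr", "pyruvate", 3),
    metabolite("accoa", "acetyl-CoA", 2),
    metabolite("glx", "glyoxylate", 2),
    metabolite("icit", "citrate/isocitrate (lumped)", 6),
    metabolite("akg", "2-ketoglutarate", 5),
    metabolite("succ", "succinate", 4, symmetric = TRUE),
    metabolite("fum", "fumarate", 4, symmetric = TRUE),
    metabolite("mal", "malate", 4),
    metabolite("oaa", "oxaloacetate", 4),
    metabolite("upper3", "upper-metabolism 3C unit (lumped)", 3),
    metabolite("atp", "ATP (net)", 0),
    metabolite("nadh", "NADH (net)", 0),
    metabolite("nadph", "NADPH (net)", 0),
    metabolite("fadh2", "FADH2 (net)", 0),
    metabolite("biomass", "biomass", 0)
  )
  names(mets) <- vapply(mets, `[[`, "", "id")
  mets
}

core_reactions <- function(params = default_cofactor_params()) {
  id1 <- function(a, b) am(a, 1, b, 1)
  rxns <- list(
    # --- exchanges and transport (uptake-positive convention) ---
    reaction("EX_for", c(for_e = 1), bounds = c(0, 0), enzyme_label = "EX"),
    reaction("T_for", c(for_e = -1, "for" = 1), atom_map = id1("for_e", "for"),
             enzyme_label = "FormT"),
    reaction("EX_co2", c(co2_e = 1), reversible = TRUE, enzyme_label = "EX"),
    reaction("T_co2", c(co2_e = -1, co2 = 1), reversible = TRUE,
             atom_map = id1("co2_e", "co2"), enzyme_label = "CO2T"),
    reaction("EX_ace", c(ace_e = 1), bounds = c(0, 0), enzyme_label = "EX"),
    reaction("T_ace", c(ace_e = -1, ace = 1),
             atom_map = am("ace_e", 1, "ace", 1, "ace_e", 2, "ace", 2),
             enzyme_label = "AceT"),
    reaction("EX_meoh", c(meoh_e = 1), bounds = c(0, 0), enzyme_label = "EX"),
    reaction("T_meoh", c(meoh_e = -1, meoh = 1),
             atom_map = id1("meoh_e", "meoh"), enzyme_label = "MeohT"),
    # --- rGlyP module M1: formate -> methylene-THF (FtfL + Fch + MtdA) ---
    reaction("FtfL", c("for" = -1, atp = -1, nadph = -1, methf = 1),
             atom_map = id1("for", "methf")),
    # --- M2: reverse glycine cleavage system ---
    reaction("GcvTHP", c(co2 = -1, methf = -1, nadh = -1, gly = 1),
             atom_map = am("co2", 1, "gly", 1, "methf", 1, "gly", 2)),
    # --- M3: serine hydroxymethyltransferase + serine deaminase ---
    reaction("GlyA", c(gly = -1, methf = -1, ser = 1),
             atom_map = am("gly", 1, "ser", 1, "gly", 2, "ser", 2,
                           "methf", 1, "ser", 3)),
    reaction("TdcG", c(ser = -1, pyr = 1),
             atom_map = am("ser", 1, "pyr", 1, "ser", 2, "pyr", 2,
                           "ser", 3, "pyr", 3)),
    # --- canonical serine/glycine biosynthesis (knocked out in rGlyP strains) ---
    reaction("SerA", c(upper3 = -1, ser = 1, nadh = 1)),
    reaction("LtaE", c(oaa = -1, atp = -2, nadph = -2, gly = 1, accoa = 1),
             atom_map = am("oaa", 1, "gly", 1, "oaa", 2, "gly", 2,
                           "oaa", 3, "accoa", 1, "oaa", 4, "accoa", 2)),
    # --- glycine oxidase branch (2-iminoacetate -> glyoxylate + NH3) ---
    reaction("ThiO", c(gly = -1, glx = 1),
             atom_map = am("gly", 1, "glx", 1, "gly", 2, "glx", 2)),
    # --- C1 oxidation: EGM and methanol oxidation ---
    reaction("Fdh", c("for" = -1, co2 = 1, nadh = 1),
             atom_map = id1("for", "co2")),
    reaction("Mdh", c(meoh = -1, fald = 1, nadh = 1),
             atom_map = id1("meoh", "fald")),
    reaction("FaldDH", c(fald = -1, "for" = 1, nadh = 1),
             atom_map = id1("fald", "for")),
    # --- acetate activation, PDH, anaplerosis ---
    reaction("ACS", c(ace = -1, atp = -2, accoa = 1),
             atom_map = am("ace", 1, "accoa", 1, "ace", 2, "accoa", 2)),
    reaction("PDH", c(pyr = -1, accoa = 1, co2 = 1, nadh = 1),
             atom_map = am("pyr", 1, "co2", 1, "pyr", 2, "accoa", 1,
                           "pyr", 3, "accoa", 2)),
    reaction("Pyc", c(pyr = -1, co2 = -1, atp = -1, oaa = 1),
             atom_map = am("pyr", 1, "oaa", 1, "pyr", 2, "oaa", 2,
                           "pyr", 3, "oaa", 3, "co2", 1, "oaa", 4)),
    # --- TCA cycle (citrate synthase + aconitase lumped into GltA) ---
    reaction("GltA", c(oaa = -1, accoa = -1, icit = 1),
             atom_map = am("oaa", 1, "icit", 1, "oaa", 2, "icit", 2,
                           "oaa", 3, "icit", 3, "oaa", 4, "icit", 4,
                           "accoa", 1, "icit", 5, "accoa", 2, "icit", 6)),
    # IDH: CO2 from the OAA C1 carboxyl; 2KG C1..C5 =
    # [OAA C4, OAA C3, OAA C2, AcCoA C2, AcCoA C1]
    reaction("Icd", c(icit = -1, akg = 1, co2 = 1, nadph = 1),
             atom_map = am("icit", 1, "co2", 1, "icit", 4, "akg", 1,
                           "icit", 3, "akg", 2, "icit", 2, "akg", 3,
                           "icit", 6, "akg", 4, "icit", 5, "akg", 5)),
    # KGDH + succinyl-CoA synthetase lumped; CO2 from 2KG C1
    reaction("SucAB", c(akg = -1, succ = 1, co2 = 1, nadh = 1, atp = 1),
             atom_map = am("akg", 1, "co2", 1, "akg", 2, "succ", 1,
                           "akg", 3, "succ", 2, "akg", 4, "succ", 3,
                           "akg", 5, "succ", 4)),
    reaction("Sdh", c(succ = -1, fum = 1, fadh2 = 1),
             atom_map = am("succ", 1, "fum", 1, "succ", 2, "fum", 2,
                           "succ", 3, "fum", 3, "succ", 4, "fum", 4)),
    reaction("FumC", c(fum = -1, mal = 1),
             atom_map = am("fum", 1, "mal", 1, "fum", 2, "mal", 2,
                           "fum", 3, "mal", 3, "fum", 4, "mal", 4)),
    reaction("MalDH", c(mal = -1, oaa = 1, nadh = 1),
             atom_map = am("mal", 1, "oaa", 1, "mal", 2, "oaa", 2,
                           "mal", 3, "oaa", 3, "mal", 4, "oaa", 4)),
    reaction("MaeB", c(mal = -1, pyr = 1, co2 = 1, nadph = 1),
             atom_map = am("mal", 1, "pyr", 1, "mal", 2, "pyr", 2,
                           "mal", 3, "pyr", 3, "mal", 4, "co2", 1)),
    # --- glyoxylate shunt ---
    # isocitrate lyase: glyoxylate = [OAA C4, OAA C3]; succinate keeps
    # [OAA C1, OAA C2, AcCoA C2, AcCoA C1]
    reaction("AceA", c(icit = -1, succ = 1, glx = 1),
             atom_map = am("icit", 4, "glx", 1, "icit", 3, "glx", 2,
                           "icit", 1, "succ", 1, "icit", 2, "succ", 2,
                           "icit", 6, "succ", 3, "icit", 5, "succ", 4)),
    # malate synthase: AcCoA methyl attacks the glyoxylate aldehyde
    reaction("GlcB", c(glx = -1, accoa = -1, mal = 1),
             atom_map = am("glx", 1, "mal", 1, "glx", 2, "mal", 2,
                           "accoa", 2, "mal", 3, "accoa", 1, "mal", 4)),
    # --- redox / energy ---
    reaction("Pnt", c(nadh = -1, nadph = 1), reversible = TRUE,
             enzyme_label = "PntAB"),
    reaction("NuoOx", c(nadh = -1, atp = params$po_nadh),
             enzyme_label = "Nuo"),
    reaction("FadOx", c(fadh2 = -1, atp = params$po_fadh2),
             enzyme_label = "ETF"),
    reaction("NGAM", c(atp = -1), bounds = c(params$ngam, params$ngam),
             enzyme_label = "maintenance"),
    # formate + ATP drain into purine synthesis (PurT)
    reaction("PurT", c("for" = -1, atp = -1)),
    # lumped gluconeogenesis / PP pathway feed (pyruvate -> 3C upper unit)
    reaction("GluNeo", c(pyr = -1, atp = -3, nadh = -1, upper3 = 1),
             enzyme_label = "gluconeogenesis"),
    reaction("BIOMASS",
             c(-biomass_coefficients(),
               atp = -params$gam, biomass = 1),
             enzyme_label = "biomass"),
    reaction("EX_biomass", c(biomass = -1), enzyme_label = "EX"),
    reaction("DM_pyr", c(pyr = -1), bounds = c(0, 0), enzyme_label = "demand")
  )
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  rxns
}

# enzyme_label -> reaction ids affected by a knockout
knockout_targets <- function() {
  list(SerA = "SerA", LtaE = "LtaE", AceA = "AceA", ThiO = "ThiO",
       PurT = "PurT", GlcB = "GlcB", Pyc = "Pyc", FtfL = "FtfL",
       GcvTHP = "GcvTHP", GlyA = "GlyA", TdcG = "TdcG", Fdh = "Fdh",
       Mdh = c("Mdh", "FaldDH"), MaeB = "MaeB")
}

# module name -> reaction ids it switches on (heterologous content only;
# M2-overexpr and M3 are genotype notes on native reactions)
module_gates <- function() {
  list("M1" = "FtfL", "EGM-Fdh" = "Fdh", "Mdh" = c("Mdh", "FaldDH"),
       "M2-overexpr" = character(0), "M3" = character(0))
}

#' Strain configuration
#'
#' Describes a strain as a set of enzyme knockouts plus a set of enabled
#' heterologous modules. Preset names: `"KT2440-core"`, `"rG1"`, `"rG1.T"`,
#' `"rG.F"`, `"rG.M"` (a middle dot may be used in place of `.`).
#'
#' @param name strain name (preset or user-defined).
#' @param knockouts character vector of enzyme labels fixed to zero flux.
#' @param additions character vector of enabled module names.
#' @return a `c1_strain_config`.
#' @export
strain_config <- function(name, knockouts = character(),
                          additions = character()) {
  name <- gsub("·", ".", name)
  if (missing(knockouts) && missing(additions)) {
    presets <- strain_presets()
    if (!name %in% names(presets)) {
      stop("unknown strain name: ", name,
           " (presets: ", paste(names(presets), collapse = ", "), ")")
    }
    return(presets[[name]])
  }
  bad_ko <- setdiff(knockouts, names(knockout_targets()))
  if (length(bad_ko) > 0) {
    stop("unknown knockout enzyme label(s): ", paste(bad_ko, collapse = ", "))
  }
  bad_mod <- setdiff(additions, names(module_gates()))
  if (length(bad_mod) > 0) {
    stop("unknown module(s): ", paste(bad_mod, collapse = ", "))
  }
  if (name == "rG.F" && !"EGM-Fdh" %in% additions) {
    stop("strain rG.F requires the EGM-Fdh module")
  }
  if (name == "rG.M" && !"Mdh" %in% additions) {
    stop("strain rG.M requires the Mdh module")
  }
  structure(list(name = name, knockouts = unique(knockouts),
                 additions = unique(additions)),
            class = "c1_strain_config")
}

#' Packaged strain presets
#' @return named list of `c1_strain_config` objects.
#' @export
strain_presets <- function() {
  rglyp_ko <- c("SerA", "LtaE", "AceA")
  list(
    "KT2440-core" = structure(list(name = "KT2440-core",
                                   knockouts = character(),
                                   additions = character()),
                              class = "c1_strain_config"),
    "rG1" = strain_config("rG1", rglyp_ko,
                          c("M1", "M2-overexpr", "M3")),
    "rG1.T" = strain_config("rG1.T", c(rglyp_ko, "ThiO"),
                            c("M1", "M2-overexpr", "M3")),
    "rG.F" = strain_config("rG.F", c(rglyp_ko, "PurT"),
                           c("M1", "M2-overexpr", "M3", "EGM-Fdh")),
    "rG.M" = strain_config("rG.M", c(rglyp_ko, "PurT"),
                           c("M1", "M2-overexpr", "M3", "Mdh"))
  )
}

#' Build the core metabolic model for a strain
#'
#' Assembles the packaged reaction library, gates heterologous modules by
#' the configured additions (absent modules get `[0, 0]` bounds), applies
#' knockouts by fixing bounds to `[0, 0]`, assembles the stoichiometric
#' matrix and validates carbon atom maps.
#'
#' @param config a `c1_strain_config` or a preset strain name.
#' @param cofactor_params see [default_cofactor_params()].
#' @return a `c1_model` with fields `metabolites`, `reactions`, `S`,
#'   `biomass_reaction_id`, `cofactor_params`, `strain`.
#' @export
build_core_model <- function(config = "KT2440-core",
                             cofactor_params = default_cofactor_params()) {
  if (is.character(config)) config <- strain_config(config)
  stopifnot(inherits(config, "c1_strain_config"))
  mets <- core_metabolites()
  rxns <- core_reactions(cofactor_params)

  gates <- module_gates()
  gated <- unlist(gates, use.names = FALSE)
  off <- setdiff(gated, unlist(gates[config$additions], use.names = FALSE))
  for (id in off) rxns[[id]]$bounds <- c(0, 0)

  targets <- knockout_targets()
  for (ko in config$knockouts) {
    ids <- targets[[ko]]
    if (is.null(ids) || !all(ids %in% names(rxns))) {
      stop("knockout targets a reaction absent from the base library: ", ko)
    }
    for (id in ids) rxns[[id]]$bounds <- c(0, 0)
  }

  model <- structure(list(metabolites = mets, reactions = rxns,
                          S = NULL, biomass_reaction_id = "BIOMASS",
                          cofactor_params = cofactor_params,
                          strain = config),
                     class = "c1_model")
  model$S <- build_S(model)
  viol <- validate_atom_maps(model)
  if (length(viol) > 0) {
    stop("atom-map carbon imbalance at build time:\n  ",
         paste(vapply(viol, `[[`, "", "message"), collapse = "\n  "))
  }
  model
}

# stoichiometric matrix (rows = metabolites, columns = reactions)
build_S <- function(model) {
  mids <- names(model$metabolites)
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in model$reactions) {
    st <- r$stoichiometry
    if (any(!names(st) %in% mids)) {
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(setdiff(names(st), mids), collapse = ", "))
    }
    S[names(st), r$id] <- st
  }
  S
}

#' Validate carbon atom maps
#'
#' Checks, for every reaction that carries an atom map, that the map is a
#' bijection from all substrate carbons onto all product carbons (carbon
#' count conserved, every carbon mapped exactly once). Reports violations;
#' never throws.
#'
#' @param model a `c1_model`.
#' @return list of violations, each `list(reaction=, message=)`; empty when
#'   the model is clean.
#' @export
validate_atom_maps <- function(model) {
  viol <- list()
  add <- function(rid, msg) {
    viol[[length(viol) + 1L]] <<- list(reaction = rid, message = paste0(rid, ": ", msg))
  }
  nC <- vapply(model$metabolites, `[[`, 0L, "n_carbons")
  for (r in model$reactions) {
    if (is.null(r$atom_map)) next
    st <- r$stoichiometry
    subs <- names(st)[st < 0 & nC[names(st)] > 0]
    prods <- names(st)[st > 0 & nC[names(st)] > 0]
    need_sub <- unlist(lapply(subs, function(m) paste0(m, ".", seq_len(nC[[m]]))))
    need_prod <- unlist(lapply(prods, function(m) paste0(m, ".", seq_len(nC[[m]]))))
    got_sub <- vapply(r$atom_map, function(e) paste0(e$sub, ".", e$si), "")
    got_prod <- vapply(r$atom_map, function(e) paste0(e$prod, ".", e$pi), "")
    if (length(need_sub) != length(need_prod)) {
      add(r$id, sprintf("carbon count not conserved (%d in, %d out)",
                        length(need_sub), length(need_prod)))
    }
    for (x in setdiff(need_sub, got_sub)) add(r$id, paste0("unmapped substrate carbon ", x))
    for (x in setdiff(got_sub, need_sub)) add(r$id, paste0("map names absent substrate carbon ", x))
    for (x in setdiff(need_prod, got_prod)) add(r$id, paste0("unmapped product carbon ", x))
    for (x in setdiff(got_prod, need_prod)) add(r$id, paste0("map names absent product carbon ", x))
    if (anyDuplicated(got_sub)) add(r$id, "substrate carbon mapped twice")
    if (anyDuplicated(got_prod)) add(r$id, "product carbon assigned twice")
  }
  viol
}

#' @export
print.c1_model <- function(x, ...) {
  cat("c1flux core model (strain ", x$strain$name, ")\n", sep = "")
  cat("  metabolites:", length(x$metabolites),
      " reactions:", length(x$reactions), "\n")
  nko <- sum(vapply(x$reactions, function(r) all(r$bounds == 0), TRUE))
  cat("  reactions with [0,0] bounds:", nko, "\n")
  invisible(x)
}

#' Export a model to the package JSON schema
#'
#' Atom maps are serialised as `["sub", i, "prod", j]` records.
#'
#' @param model a `c1_model`.
#' @param path output path; when `NULL` the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(
    strain = model$strain$name,
    cofactor_params = model$cofactor_params,
    biomass_reaction_id = model$biomass_reaction_id,
    metabolites = lapply(unname(model$metabolites), function(m) {
      list(id = m$id, name = m$name, n_carbons = m$n_carbons,
           compartment = m$compartment, symmetric = m$symmetric)
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id,
           stoichiometry = as.list(r$stoichiometry),
           reversible = r$reversible, bounds = r$bounds,
           enzyme_label = r$enzyme_label,
           atom_map = if (is.null(r$atom_map)) NULL else
             lapply(r$atom_map, function(e) list(e$sub, e$si, e$prod, e$pi)))
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a model from the package JSON schema
#' @param path JSON file path or literal JSON string.
#' @return a `c1_model`.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- lapply(obj$metabolites, function(m) {
    metabolite(m$id, m$name, m$n_carbons, m$compartment,
               isTRUE(m$symmetric))
  })
  names(mets) <- vapply(mets, `[[`, "", "id")
  rxns <- lapply(obj$reactions, function(r) {
    amap <- if (is.null(r$atom_map)) NULL else
      lapply(r$atom_map, function(e) {
        list(sub = e[[1]], si = as.integer(e[[2]]),
             prod = e[[3]], pi = as.integer(e[[4]]))
      })
    reaction(r$id, unlist(r$stoichiometry), isTRUE(r$reversible),
             unlist(r$bounds), amap, r$enzyme_label)
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  strain <- tryCatch(strain_config(obj$strain),
                     error = function(e) structure(
                       list(name = obj$strain, knockouts = character(),
                            additions = character()),
                       class = "c1_strain_config"))
  model <- structure(list(metabolites = mets, reactions = rxns, S = NULL,
                          biomass_reaction_id = obj$biomass_reaction_id,
                          cofactor_params = obj$cofactor_params,
                          strain = strain),
                     class = "c1_model")
  model$S <- build_S(model)
  model
}

#' Write a model summary as TSV
#' @param model a `c1_model`.
#' @param path output TSV path.
#' @export
model_summary_tsv <- function(model, path) {
  df <- data.frame(
    reaction = names(model$reactions),
    enzyme = vapply(model$reactions, `[[`, "", "enzyme_label"),
    reversible = vapply(model$reactions, `[[`, TRUE, "reversible"),
    lb = vapply(model$reactions, function(r) r$bounds[1], 0),
    ub = vapply(model$reactions, function(r) r$bounds[2], 0),
    has_atom_map = !vapply(model$reactions, function(r) is.null(r$atom_map), TRUE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
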