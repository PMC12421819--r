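# SBML Level-3 FBC import, for extending a genome-scale reconstruction
# with the rGlyP reactions. Only the constraint-based subset is read:
# species, reactions with stoichiometries, flux bounds (fbc parameters)
# and the active objective. No atom maps are available on this route; it
# serves full-model FBA only.

#' Read an SBML Level-3 FBC model
#'
#' @param path SBML file path.
#' @return a `c1_model` (atom maps absent, `n_carbons = 0` throughout).
#' @export
read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable SBML: ", conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- lapply(sp, function(n) {
    id <- xml2::xml_attr(n, "id")
    bc <- identical(xml2::xml_attr(n, "boundaryCondition"), "true")
    metabolite(id, xml2::xml_attr(n, "name") %||% id, 0L,
               if (bc) "external" else "cytosol")
  })
  names(mets) <- vapply(mets, `[[`, "", "id")
  boundary <- vapply(sp, function(n)
    identical(xml2::xml_attr(n, "boundaryCondition"), "true"), TRUE)
  boundary_ids <- names(mets)[boundary]
  mets <- mets[!boundary]  # boundary species are not balanced

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx, function(n) {
    id <- xml2::xml_attr(n, "id")
    reac <- xml2::xml_find_all(n, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(n, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      xml2::xml_attr(reac, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "species")))
    st <- st[!names(st) %in% boundary_ids]
    lb <- pval[xml2::xml_attr(n, "fbc:lowerFluxBound", ns = ns)]
    ub <- pval[xml2::xml_attr(n, "fbc:upperFluxBound", ns = ns)]
    if (is.na(lb)) lb <- if (identical(xml2::xml_attr(n, "reversible"), "true")) -1000 else 0
    if (is.na(ub)) ub <- 1000
    reaction(id, st, reversible = lb < 0, bounds = c(lb, ub))
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")

  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  biomass <- if (inherits(fo, "xml_missing")) {
    grep("biomass", names(rxns), ignore.case = TRUE, value = TRUE)[1]
  } else xml2::xml_attr(fo, "fbc:reaction", ns = ns)

  model <- structure(list(metabolites = mets, reactions = rxns, S = NULL,
                          biomass_reaction_id = biomass,
                          cofactor_params = list(),
                          strain = structure(list(name = "genome-scale",
                                                  knockouts = character(),
                                                  additions = character()),
                                             class = "c1_strain_config")),
                     class = "c1_model")
  model$S <- build_S(model)
  model
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
}

#' Extend a genome-scale model with rGlyP edits
#'
#' Applies knockout bounds (`[0, 0]`) to the named reactions and appends
#' additional reactions (e.g. the heterologous formate-THF ligase,
#' methenyl-THF cyclohydrolase and methylene-THF dehydrogenase steps, plus
#' a formate or methanol dehydrogenase).
#'
#' @param sbml an SBML path or a `c1_model` from [read_sbml_model()].
#' @param knockouts character vector of reaction ids to bound to zero.
#' @param additions list of `c1_reaction` objects to append; their
#'   stoichiometries may only reference species present in the model.
#' @return the edited `c1_model`.
#' @export
extend_genome_scale_model <- function(sbml, knockouts = character(),
                                      additions = list()) {
  model <- if (inherits(sbml, "c1_model")) sbml else read_sbml_model(sbml)
  missing_ko <- setdiff(knockouts, names(model$reactions))
  if (length(missing_ko) > 0) {
    stop("missing reaction identifiers: ", paste(missing_ko, collapse = ", "))
  }
  for (id in knockouts) model$reactions[[id]]$bounds <- c(0, 0)
  for (r in additions) {
    stopifnot(inherits(r, "c1_reaction"))
    unknown <- setdiff(names(r$stoichiometry), names(model$metabolites))
    if (length(unknown) > 0) {
      stop("added reaction ", r$id, " references unknown species: ",
           paste(unknown, collapse = ", "))
    }
    model$reactions[[r$id]] <- r
  }
  model$S <- build_S(model)
  model
}
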