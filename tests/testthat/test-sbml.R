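# SBML L3 FBC import on a small synthetic document built in code
# (stand-in for a genome-scale reconstruction, which is not bundled).

sbml_toy <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
'<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
'level="3" version="1" fbc:required="false">\n',
'<model id="toy_synthetic">\n',
'<listOfSpecies>\n',
'<species id="A" boundaryCondition="false"/>\n',
'<species id="B" boundaryCondition="false"/>\n',
'<species id="A_ext" boundaryCondition="true"/>\n',
'</listOfSpecies>\n',
'<listOfParameters>\n',
'<parameter id="lb_zero" value="0"/>\n',
'<parameter id="ub_ten" value="10"/>\n',
'<parameter id="ub_big" value="1000"/>\n',
'</listOfParameters>\n',
'<listOfReactions>\n',
'<reaction id="R_up" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">\n',
'<listOfReactants><speciesReference species="A_ext" stoichiometry="1"/></listOfReactants>\n',
'<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>\n',
'</reaction>\n',
'<reaction id="R_conv" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">\n',
'<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>\n',
'<listOfProducts><speciesReference species="B" stoichiometry="0.5"/></listOfProducts>\n',
'</reaction>\n',
'<reaction id="R_biomass" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">\n',
'<listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>\n',
'</reaction>\n',
'</listOfReactions>\n',
'<fbc:listOfObjectives fbc:activeObjective="obj">\n',
'<fbc:objective fbc:id="obj" fbc:type="maximize">\n',
'<fbc:listOfFluxObjectives>\n',
'<fbc:fluxObjective fbc:reaction="R_biomass" fbc:coefficient="1"/>\n',
'</fbc:listOfFluxObjectives>\n',
'</fbc:objective>\n',
'</fbc:listOfObjectives>\n',
'</model>\n</sbml>\n')
}

write_toy_sbml <- function() {
  path <- withr::local_tempfile(fileext = ".xml",
                                .local_envir = parent.frame())
  writeLines(sbml_toy(), path)
  path
}

test_that("SBML import reads species, bounds and the objective", {
  m <- read_sbml_model(write_toy_sbml())
  expect_equal(length(m$reactions), 3)
  expect_equal(m$biomass_reaction_id, "R_biomass")
  expect_equal(m$reactions$R_up$bounds, c(0, 10))
  # boundary species are dropped from the balance
  expect_false("A_ext" %in% rownames(m$S))
  expect_equal(unname(m$S["B", "R_conv"]), 0.5)
})

test_that("FBA on the imported model equals the closed form", {
  m <- read_sbml_model(write_toy_sbml())
  fd <- solve_fba(m, NULL, objective = "R_biomass")
  # uptake cap 10, half lost in conversion -> biomass flux 5
  expect_equal(fd$mu, 5, tolerance = 1e-9)
})

test_that("edits: empty set is identity; counts change as expected", {
  m <- read_sbml_model(write_toy_sbml())
  m_same <- extend_genome_scale_model(m)
  expect_equal(length(m_same$reactions), length(m$reactions))
  expect_equal(m_same$S, m$S)

  added <- reaction("R_fdh", c(A = -1), bounds = c(0, 100))
  m2 <- extend_genome_scale_model(m, knockouts = "R_conv",
                                  additions = list(added))
  expect_equal(length(m2$reactions), length(m$reactions) + 1)
  expect_equal(m2$reactions$R_conv$bounds, c(0, 0))
  # knocked-out conversion leaves only the added drain; biomass infeasible
  fd <- solve_fba(m2, NULL, objective = "R_biomass", parsimonious = FALSE)
  expect_equal(fd$mu, 0, tolerance = 1e-9)
})

test_that("edit errors are explicit", {
  m <- read_sbml_model(write_toy_sbml())
  expect_error(extend_genome_scale_model(m, knockouts = "R_missing"),
               "missing reaction identifiers")
  expect_error(extend_genome_scale_model(
    m, additions = list(reaction("R_x", c(nonexistent = -1)))),
    "unknown species")
  expect_error(read_sbml_model(tempfile()), "unreadable SBML")
})
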