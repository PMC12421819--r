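test_that("model building is deterministic and applies genotype edits", {
  m1 <- build_core_model("rG1")
  m2 <- build_core_model("rG1")
  expect_identical(m1$S, m2$S)
  expect_identical(lapply(m1$reactions, `[[`, "bounds"),
                   lapply(m2$reactions, `[[`, "bounds"))

  # rG1: Delta serA ltaE aceA with M1-M3 present
  expect_equal(m1$reactions$AceA$bounds, c(0, 0))
  expect_equal(m1$reactions$SerA$bounds, c(0, 0))
  expect_equal(m1$reactions$LtaE$bounds, c(0, 0))
  expect_gt(m1$reactions$FtfL$bounds[2], 0)
  expect_gt(m1$reactions$GcvTHP$bounds[2], 0)
  # no EGM in the mixotroph
  expect_equal(m1$reactions$Fdh$bounds, c(0, 0))

  # rG.M: methanol oxidation open, Fdh closed
  mm <- build_core_model("rG.M")
  expect_gt(mm$reactions$Mdh$bounds[2], 0)
  expect_equal(mm$reactions$Fdh$bounds, c(0, 0))

  # base model: all heterologous modules closed, canonical routes open
  mb <- build_core_model("KT2440-core")
  expect_equal(mb$reactions$FtfL$bounds, c(0, 0))
  expect_gt(mb$reactions$SerA$bounds[2], 0)
})

test_that("strain configuration errors are caught", {
  expect_error(build_core_model("rG9"), "unknown strain")
  expect_error(strain_config("x", knockouts = "NotAnEnzyme"),
               "unknown knockout")
  expect_error(strain_config("rG.F", "SerA", "M1"), "EGM-Fdh")
  # middle-dot spelling resolves to the preset
  expect_equal(strain_config("rG·F")$name, "rG.F")
})

test_that("stoichiometric matrix matches reaction stoichiometries", {
  m <- build_core_model("rG.F")
  expect_equal(dim(m$S), c(length(m$metabolites), length(m$reactions)))
  for (rid in c("GcvTHP", "GltA", "BIOMASS")) {
    st <- m$reactions[[rid]]$stoichiometry
    col <- m$S[, rid]
    expect_equal(col[names(st)], st[names(st)])
    expect_true(all(col[setdiff(names(col), names(st))] == 0))
  }
  expect_true(m$biomass_reaction_id %in% names(m$reactions))
})

test_that("atom-map validation passes the library and flags imbalances", {
  m <- build_core_model("rG.F")
  expect_length(validate_atom_maps(m), 0)

  # the curated reverse-GCS map: CO2 -> glycine C1, methylene-THF -> C2
  gcs <- m$reactions$GcvTHP$atom_map
  expect_true(any(vapply(gcs, function(e)
    e$sub == "co2" && e$prod == "gly" && e$pi == 1L, TRUE)))
  expect_true(any(vapply(gcs, function(e)
    e$sub == "methf" && e$prod == "gly" && e$pi == 2L, TRUE)))

  # force a 3-carbon substrate mapped onto a 2-carbon product
  bad <- m
  bad$reactions$TdcG$stoichiometry <- c(ser = -1, accoa = 1)
  bad$reactions$TdcG$atom_map <- am_records(
    list(c("ser", 1, "accoa", 1), c("ser", 2, "accoa", 2)))
  v <- validate_atom_maps(bad)
  expect_gt(length(v), 0)
  expect_true(any(grepl("ser\\.3", vapply(v, `[[`, "", "message"))))
})

test_that("every atom-mapped reaction in the library conserves carbon", {
  m <- build_core_model("KT2440-core")
  nC <- vapply(m$metabolites, `[[`, 0L, "n_carbons")
  for (r in m$reactions) {
    if (is.null(r$atom_map)) next
    st <- r$stoichiometry
    cin <- sum(nC[names(st)[st < 0]])
    cout <- sum(nC[names(st)[st > 0]])
    expect_equal(cin, cout, info = r$id)
    expect_length(r$atom_map, cin)
  }
})

test_that("JSON model round trip preserves structure", {
  m <- build_core_model("rG.F")
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  m2 <- model_from_json(path)
  expect_identical(dimnames(m2$S), dimnames(m$S))
  expect_equal(m2$S, m$S)
  expect_equal(m2$reactions$GcvTHP$atom_map, m$reactions$GcvTHP$atom_map)
  expect_equal(m2$reactions$AceA$bounds, c(0, 0))
  expect_equal(m2$cofactor_params$po_nadh, m$cofactor_params$po_nadh)
})

test_that("model summary TSV is written with one row per reaction", {
  m <- build_core_model("rG1")
  path <- withr::local_tempfile(fileext = ".tsv")
  model_summary_tsv(m, path)
  df <- read.delim(path)
  expect_equal(nrow(df), length(m$reactions))
  expect_true(all(c("reaction", "enzyme", "lb", "ub") %in% names(df)))
})
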