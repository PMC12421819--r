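# Positional isotopomer simulation: trivial anchors, curated-map
# predictions, brute-force oracle equivalence and distribution invariants.

model_F <- build_core_model("rG.F")
model_mixo <- build_core_model("rG1")

test_that("no tracer in, no label out", {
  scen <- scenario_mixotrophic_unlabeled()
  v <- hypothesis_fluxes(model_mixo, scen, flux_hypothesis("cyclic_TCA"))
  st <- simulate_labeling(model_mixo, v, scen)
  for (a in reporter_aas) {
    mid <- amino_acid_mid(st, a)
    expect_equal(unname(mid[1]), 1, tolerance = 1e-9)
    expect_equal(dominant_isotopomer(st, a), 0L, ignore_attr = TRUE)
  }
})

test_that("pure 13C-formate with 12CO2 gives the rGlyP backbone pattern", {
  scen <- labeling_scenario(list("for" = 1, co2 = 0))
  v <- hypothesis_fluxes(model_F, scen, flux_hypothesis("anaplerosis"))
  st <- simulate_labeling(model_F, v, scen)
  # glycine: C1 unlabelled (CO2), C2 labelled (methylene-THF), prob 1
  gly <- st$dists$gly
  expect_equal(unname(gly[3]), 1, tolerance = 1e-9)  # bit pattern 10 -> index 3
  expect_equal(unname(amino_acid_mid(st, "Ser")["M2"]), 1, tolerance = 1e-9)
  expect_equal(unname(amino_acid_mid(st, "Ala")["M2"]), 1, tolerance = 1e-9)
  expect_equal(dominant_isotopomer(st, "Asp"), 2L, ignore_attr = TRUE)
})

test_that("cyclic TCA with fully labelled acetyl-CoA drives OAA to M+4", {
  scen <- labeling_scenario(list("for" = 1, ace = c(1, 1), co2 = 0))
  v <- hypothesis_fluxes(model_mixo, scen, flux_hypothesis("cyclic_TCA"))
  st <- simulate_labeling(model_mixo, v, scen)
  expect_equal(unname(st$dists$oaa[16]), 1, tolerance = 1e-6)  # all-ones pattern
  expect_equal(dominant_isotopomer(st, "Glu"), 5L, ignore_attr = TRUE)
})

test_that("fixed point matches the brute-force oracle to 1e-8", {
  cases <- list(
    list(model_mixo, scenario_mixotrophic_tracer(), "cyclic_TCA"),
    list(model_mixo, scenario_mixotrophic_tracer(), "glyoxylate_malate_synthase"),
    list(model_F, scenario_formatotrophic_12co2(), "anaplerosis"),
    list(model_F, scenario_formatotrophic_13co2(), "cyclic_TCA")
  )
  for (cs in cases) {
    scen <- cs[[2]]
    v <- hypothesis_fluxes(cs[[1]], scen, flux_hypothesis(cs[[3]]))
    st <- simulate_labeling(cs[[1]], v, scen)
    ora <- oracle_simulate(cs[[1]], v, scen)
    for (m in names(ora$mids)) {
      expect_equal(unname(st$mids[[m]]), unname(ora$mids[[m]]),
                   tolerance = 1e-8,
                   info = paste(cs[[3]], m))
    }
  }
})

test_that("distributions are normalised and MIDs are exact marginals", {
  scen <- scenario_mixotrophic_tracer()
  v <- hypothesis_fluxes(model_mixo, scen, flux_hypothesis("cyclic_TCA"))
  st <- simulate_labeling(model_mixo, v, scen)
  for (m in names(st$dists)) {
    expect_equal(sum(st$dists[[m]]), 1, tolerance = 1e-9, info = m)
    n <- as.integer(log2(length(st$dists[[m]])))
    # brute-force marginalisation over bit patterns
    counts <- vapply(0:(2^n - 1), function(b) sum(as.integer(intToBits(b))), 0L)
    brute <- vapply(0:n, function(k) sum(st$dists[[m]][counts == k]), 0)
    expect_equal(unname(st$mids[[m]]), brute, tolerance = 1e-12, info = m)
  }
})

test_that("symmetric metabolites are invariant to carbon reversal", {
  scen <- scenario_mixotrophic_tracer()
  v <- hypothesis_fluxes(model_mixo, scen, flux_hypothesis("cyclic_TCA"))
  st <- simulate_labeling(model_mixo, v, scen)
  for (m in c("succ", "fum")) {
    d <- st$dists[[m]]
    rev_idx <- c1flux:::reverse_bits_index(4L)
    expect_equal(d, d[rev_idx], tolerance = 1e-9, info = m)
  }
})

test_that("raising the CO2 13C fraction never lowers aspartate labelling", {
  expected_label <- function(f_co2) {
    scen <- labeling_scenario(list("for" = 0.99, co2 = f_co2))
    v <- hypothesis_fluxes(model_F, scen, flux_hypothesis("anaplerosis"))
    st <- simulate_labeling(model_F, v, scen)
    mid <- amino_acid_mid(st, "Asp")
    sum(mid * (seq_along(mid) - 1))
  }
  labels <- vapply(c(0, 0.2, 0.5, 0.8, 0.99), expected_label, 0)
  expect_true(all(diff(labels) >= -1e-9))
})

test_that("tracer purity 0.99 preserves the pure-tracer dominant species", {
  scens <- list(scenario_mixotrophic_tracer, scenario_formatotrophic_12co2,
                scenario_formatotrophic_13co2)
  models <- list(model_mixo, model_F, model_F)
  for (i in seq_along(scens)) {
    for (h in c("cyclic_TCA", "glyoxylate_malate_synthase", "anaplerosis")) {
      s1 <- scens[[i]](purity = 1)
      s2 <- scens[[i]](purity = 0.99)
      v1 <- hypothesis_fluxes(models[[i]], s1, flux_hypothesis(h))
      st1 <- simulate_labeling(models[[i]], v1, s1)
      st2 <- simulate_labeling(models[[i]], hypothesis_fluxes(models[[i]], s2,
                                                              flux_hypothesis(h)), s2)
      for (a in reporter_aas) {
        expect_equal(dominant_isotopomer(st2, a), dominant_isotopomer(st1, a),
                     ignore_attr = TRUE, info = paste(i, h, a))
      }
    }
  }
})

test_that("CO2 reassimilation shifts glycine toward higher labelling", {
  scen0 <- scenario_formatotrophic_12co2(co2_reassimilation = 0)
  scen5 <- scenario_formatotrophic_12co2(co2_reassimilation = 0.5)
  v <- hypothesis_fluxes(model_F, scen0, flux_hypothesis("anaplerosis"))
  st0 <- simulate_labeling(model_F, v, scen0)
  st5 <- simulate_labeling(model_F, v, scen5)
  # internally released CO2 is 13C-rich (Fdh oxidises labelled formate)
  expect_gt(amino_acid_mid(st5, "Gly")["M2"], amino_acid_mid(st0, "Gly")["M2"])
})

test_that("hypotheses are indistinguishable without tracer", {
  fp <- predict_fingerprints(model_mixo, scenario_mixotrophic_unlabeled())
  for (h in names(fp)) {
    for (a in reporter_aas) {
      expect_equal(unname(fp[[h]][[a]][1]), 1, tolerance = 1e-9)
    }
  }
})

test_that("discrimination: self-match scores zero, ties are flagged", {
  fp <- predict_fingerprints(model_F, scenario_formatotrophic_12co2())
  d <- discriminate_hypotheses(fp$anaplerosis, fp)
  expect_equal(d$best, "anaplerosis")
  expect_equal(d$scores$score[1], 0, tolerance = 1e-12)
  expect_gt(d$margin, 0)

  # symmetric midpoint between two fingerprints ties exactly
  mix <- lapply(names(fp$anaplerosis), function(a) {
    (fp$anaplerosis[[a]] + fp$cyclic_TCA[[a]]) / 2
  })
  names(mix) <- names(fp$anaplerosis)
  d2 <- discriminate_hypotheses(mix, fp[c("anaplerosis", "cyclic_TCA")])
  expect_true(d2$tie)
  expect_equal(d2$scores$score[1], d2$scores$score[2], tolerance = 1e-12)
})

test_that("errors: absent metabolites and malformed MIDs", {
  scen <- scenario_formatotrophic_12co2()
  v <- hypothesis_fluxes(model_F, scen, flux_hypothesis("anaplerosis"))
  st <- simulate_labeling(model_F, v, scen)
  expect_error(dominant_isotopomer(st, "Trp"), "absent")
  fp <- predict_fingerprints(model_F, scen)
  expect_error(discriminate_hypotheses(list(Gly = c(1, 0)), fp),
               "length mismatch")
})
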