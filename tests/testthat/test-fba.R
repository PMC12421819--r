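# FBA on the core model: trivial guards, stoichiometric bounds, frozen
# oracle fixtures and structural properties.

test_that("no substrate means no growth", {
  m <- build_core_model("rG.F")
  # with maintenance relaxed: feasible, but zero growth
  fd <- solve_fba(m, flux_constraints(list("for" = 0), maintenance = 0))
  expect_equal(fd$status, "optimal")
  expect_equal(fd$mu, 0, tolerance = 1e-9)
  # with maintenance enforced there is no feasible state at all
  fd2 <- solve_fba(m, flux_constraints(list("for" = 0)))
  expect_equal(fd2$status, "infeasible")
  expect_length(fd2$v, 0)
})

test_that("mass balance holds at the optimum", {
  m <- build_core_model("rG.F")
  fd <- solve_fba(m, flux_constraints(list("for" = 18.5)))
  expect_equal(fd$status, "optimal")
  expect_lt(max(abs(m$S %*% fd$v)), 1e-8)
})

test_that("carbon-limited bound: at most 1 pyruvate per 2 formate via M1-M3", {
  # energy costs zeroed (free cofactor pools, no maintenance, no GAM),
  # pyruvate demand as objective: 100 formate + CO2 -> at most 50 pyruvate
  m <- free_cofactors_model("rG.F")
  fd <- solve_fba(m, flux_constraints(list("for" = c(0, 100))),
                  objective = "DM_pyr", parsimonious = FALSE)
  expect_equal(fd$status, "optimal")
  expect_equal(fd$mu, 50, tolerance = 1e-6)
})

test_that("frozen fixture: rG.F at formate uptake 100, default cofactors", {
  # expected values computed before the build with an independent LP
  # oracle (scipy.optimize.linprog, HiGHS) on the exported S and bounds:
  # mu = 0.6376594629853, v_Fdh = 79.67524227681, v_GCS = 10.19171119689
  m <- build_core_model("rG.F")
  fd <- solve_fba(m, flux_constraints(list("for" = 100)))
  expect_equal(fd$mu, 0.6376594629853, tolerance = 1e-8)
  expect_equal(unname(fd$v["Fdh"]), 79.67524227681, tolerance = 1e-6)
  expect_equal(unname(fd$v["GcvTHP"]), 10.19171119689, tolerance = 1e-6)
})

test_that("flux normalisation reproduces the reported arithmetic", {
  m <- build_core_model("rG.F")
  fd <- solve_fba(m, flux_constraints(list("for" = 18.5)))
  fd <- normalize_fluxes(fd, m, "for")
  expect_equal(unname(fd$normalized["EX_for"]), 100, tolerance = 1e-9)
  # v = 14.8 at uptake 18.5 -> 80%; v = 9.25 -> 50%
  fake <- fd
  fake$v["Fdh"] <- 14.8
  fake <- normalize_fluxes(fake, m, "for")
  expect_equal(unname(fake$normalized["Fdh"]), 80, tolerance = 1e-9)
  fake$v["Fdh"] <- 9.25
  fake <- normalize_fluxes(fake, m, "for")
  expect_equal(unname(fake$normalized["Fdh"]), 50, tolerance = 1e-9)
  # percentages invariant to uniform rescaling
  sc <- fd; sc$v <- sc$v * 3.7
  sc <- normalize_fluxes(sc, m, "for")
  expect_equal(sc$normalized, fd$normalized, tolerance = 1e-9)
})

test_that("normalisation refuses zero uptake", {
  m <- build_core_model("rG.F")
  fd <- solve_fba(m, flux_constraints(list("for" = 0), maintenance = 0))
  expect_error(normalize_fluxes(fd, m, "for"), "zero uptake")
})

test_that("theoretical yield guards and monotonicity", {
  m <- build_core_model("rG.F")
  expect_error(theoretical_yield(m, "for", 0), "positive")
  expect_error(theoretical_yield(m, "glucose", 10), "not exchangeable")
  y_maint <- theoretical_yield(m, "for", 18.5)
  params0 <- default_cofactor_params(); params0$ngam <- 0
  y_free <- theoretical_yield(build_core_model("rG.F", params0), "for", 18.5)
  expect_gte(y_free, y_maint)
  expect_gt(y_maint, 0)
})

test_that("optimum is monotone under 20 random bound relaxations", {
  set.seed(7)
  m <- build_core_model("rG.F")
  base <- solve_fba(m, flux_constraints(list("for" = c(0, 18.5))),
                    parsimonious = FALSE)$mu
  open_ids <- names(Filter(function(r) r$bounds[2] > 0, m$reactions))
  for (i in 1:20) {
    m2 <- m
    rid <- sample(open_ids, 1)
    m2$reactions[[rid]]$bounds[2] <- m2$reactions[[rid]]$bounds[2] * stats::runif(1, 1.5, 4)
    relaxed <- solve_fba(m2, flux_constraints(list("for" = c(0, 18.5))),
                         parsimonious = FALSE)$mu
    expect_gte(relaxed + 1e-9, base)
  }
})

test_that("knockouts force zero flux in every optimal solution", {
  for (ko in list(c("rG1", "AceA"), c("rG1.T", "ThiO"), c("rG.F", "SerA"))) {
    m <- build_core_model(ko[1])
    cons <- flux_constraints(list("for" = 12.9, ace = if (ko[1] == "rG.F") 0 else 6.45))
    fd <- solve_fba(m, cons)
    if (fd$status == "optimal") {
      expect_equal(unname(fd$v[ko[2]]), 0, info = paste(ko, collapse = "/"))
    }
  }
})

test_that("methylotroph grows on methanol without the EGM", {
  m <- build_core_model("rG.M")
  fd <- solve_fba(m, flux_constraints(list(meoh = 5.83)))
  expect_equal(fd$status, "optimal")
  expect_gt(fd$mu, 0.05)
  expect_equal(unname(fd$v["Fdh"]), 0)
  expect_gt(unname(fd$v["Mdh"]), 0)
})
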