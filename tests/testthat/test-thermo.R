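# Small reversible toy for sign-forcing: A <-> B with an outlet for both.
sign_toy <- function(dGr0) {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     compartment = "c", formula = "C2H4",
                     stringsAsFactors = FALSE)
  rxns <- list(
    reaction("EX_A", c(A_c = -1), lower_bound = -10, upper_bound = 0,
             kind = "exchange"),
    reaction("R1", c(A_c = -1, B_c = 1), lower_bound = -1000),
    reaction("BIOMASS", c(B_c = -1), lower_bound = 0, kind = "biomass"))
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  list(model = metabolic_model(mets, rxns, c(c = "cytosol"), "BIOMASS",
                               id = "sign_toy"),
       thermo = thermo_annotation(dGr_std = c(R1 = dGr0)))
}

test_that("a strongly positive reaction Gibbs energy forbids forward flux", {
  # concentration span gives RT*ln-range of about +/-34.8 kJ/mol per
  # metabolite pair; +50 kJ/mol cannot be overcome
  st <- sign_toy(50)
  s <- solve_tfa(st$model, st$thermo)
  expect_equal(s$objective_value, 0, tolerance = 1e-6)
  expect_equal(unname(s$fluxes["R1"]), 0, tolerance = 1e-6)
  # and the mirrored case drives it forward freely
  st2 <- sign_toy(-50)
  expect_equal(solve_tfa(st2$model, st2$thermo)$objective_value, 10)
  # a mild value within the concentration span stays feasible
  st3 <- sign_toy(10)
  expect_equal(solve_tfa(st3$model, st3$thermo)$objective_value, 10)
})

test_that("with an empty annotation TFA equals FBA exactly", {
  for (seed in 1:5) {
    gen <- generate_toy_model(synthetic_spec(seed = seed))
    expect_identical(solve_tfa(gen$model, thermo_annotation())$objective_value,
                     solve_fba(gen$model)$objective_value)
  }
})

test_that("thermodynamic constraints only remove solutions (TFA <= FBA)", {
  for (seed in 1:8) {
    gen <- generate_toy_model(synthetic_spec(seed = seed))
    fba <- solve_fba(gen$model)$objective_value
    tfa <- solve_tfa(gen$model, gen$thermo)$objective_value
    expect_lte(tfa, fba + 1e-7)
  }
})

test_that("direction coupling holds in every TFA solution", {
  for (seed in c(3, 9)) {
    gen <- generate_toy_model(synthetic_spec(seed = seed))
    s <- solve_tfa(gen$model, gen$thermo)
    expect_equal(s$status, "optimal")
    for (rid in names(s$dG)) {
      if (s$fluxes[rid] > 1e-6)
        expect_lte(s$dG[rid], 1e-6)
    }
  }
})

test_that("TFA optimum equals exhaustive direction-pattern enumeration", {
  # small chain with few covered reactions so all 2^k patterns are checked
  for (seed in 1:5) {
    set.seed(seed + 100)
    n <- 6
    mets <- data.frame(id = sprintf("M%d_c", 0:n),
                       name = sprintf("M%d", 0:n), compartment = "c",
                       formula = "C2H4", stringsAsFactors = FALSE)
    rxns <- list(reaction("EX_M0", c(M0_c = -1), lower_bound = -10,
                          upper_bound = 0, kind = "exchange"))
    for (i in seq_len(n))
      rxns[[sprintf("R%d", i)]] <-
        reaction(sprintf("R%d", i),
                 setNames(c(-1, 1), sprintf("M%d_c", c(i - 1, i))),
                 lower_bound = 0)
    rxns$BIOMASS <- reaction("BIOMASS", setNames(-1, sprintf("M%d_c", n)),
                             lower_bound = 0, kind = "biomass")
    names(rxns)[1] <- "EX_M0"
    m <- metabolic_model(mets, rxns, c(c = "cytosol"), "BIOMASS")
    dGr <- setNames(runif(n, -40, 40), sprintf("R%d", seq_len(n)))
    covered <- sample(names(dGr), 4)
    th <- thermo_annotation(dGr_std = dGr[covered])
    mine <- solve_tfa(m, th)
    orac <- oracle_tfa_enum(m, th, "BIOMASS")
    expect_equal(mine$objective_value, orac$objective, tolerance = 1e-6)
  }
})

test_that("thermo annotations round-trip through TSV", {
  th <- thermo_annotation(dGf_std = c(A_c = -120.5, B_c = -80.25),
                          dGr_std = c(R1 = 12.5))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_thermo_tsv(th, p)
  th2 <- read_thermo_tsv(p)
  expect_equal(th2$dGf_std[sort(names(th2$dGf_std))],
               th$dGf_std[sort(names(th$dGf_std))])
  expect_equal(th2$dGr_std, th$dGr_std)
})
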