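test_that("genotype enumeration follows the equal-genotype model", {
  lgr <- enumerate_genotypes(marking_system("LGR"))
  expect_equal(nrow(lgr), 9L)
  expect_true(all(abs(lgr$probability - 1 / 9) < 1e-12))
  expect_equal(sum(lgr$probability), 1, tolerance = 1e-12)

  gneg <- enumerate_genotypes(marking_system("GFPNEG_FRT19A"))
  expect_equal(nrow(gneg), 3L)
  expect_setequal(gneg$X, c("GFP/GFP", "GFP/none", "none/none"))
  expect_equal(sum(gneg$probability), 1, tolerance = 1e-12)

  expect_error(marking_system("FRT82B"), "unknown marking system")
})

test_that("genotype-to-phenotype mapping applies dominance (and MARCM inversion)", {
  lgr <- marking_system("LGR")
  het <- list(`2L` = c("GFP", "LacZ"), `2R` = c("RFP", "none"))
  expect_equal(genotype_to_phenotype(lgr, het), "BGR")
  homo <- list(`2L` = c("LacZ", "LacZ"), `2R` = c("none", "none"))
  expect_equal(genotype_to_phenotype(lgr, homo), "B")

  marcm <- marking_system("MARCM_FRT19A")
  expect_equal(genotype_to_phenotype(marcm, list(X = c("GAL80", "none"))),
               "GFP-")  # repressor still present: unlabelled
  expect_equal(genotype_to_phenotype(marcm, list(X = c("none", "none"))),
               "GFP+")

  expect_error(genotype_to_phenotype(lgr, list(`2L` = c("RFP", "RFP"),
                                               `2R` = c("none", "none"))),
               "not valid for arm")
})

test_that("LGR phenotype distribution is 1:1:1:2:2:2 over six classes", {
  pd <- phenotype_distribution(marking_system("LGR"))
  expect_equal(nrow(pd), 6L)
  expected <- c(B = 1, G = 1, BG = 1, BR = 2, GR = 2, BGR = 2) / 9
  expect_equal(pd$probability[match(names(expected), pd$phenotype)],
               unname(expected), tolerance = 1e-12)
  expect_equal(sum(pd$probability), 1, tolerance = 1e-12)
})

test_that("single-FRT distribution is 2:1 visible phenotypes", {
  # brute force over the 3 one-arm genotypes: GFP/GFP and GFP/none
  # express GFP, none/none does not -> 2/3 vs 1/3
  pd <- phenotype_distribution(marking_system("GFPNEG_FRT19A"))
  expect_equal(pd$probability[pd$phenotype == "GFP+"], 2 / 3,
               tolerance = 1e-12)
  expect_equal(pd$probability[pd$phenotype == "GFP-"], 1 / 3,
               tolerance = 1e-12)
})

test_that("anomalous phenotypes lacking both 2L markers are flagged", {
  lgr <- marking_system("LGR")
  res <- is_canonical_phenotype(lgr, c("R", "none", "BGR", "GR"))
  expect_equal(res$canonical, c(FALSE, FALSE, TRUE, TRUE))
  expect_match(res$reason[1], "2L markers")
  expect_match(res$reason[2], "2L markers")
  expect_true(all(is.na(res$reason[3:4])))

  # every phenotype with positive mass is canonical, for every system
  for (nm in c("GFPNEG_FRT19A", "MARCM_FRT19A", "LGR")) {
    sys <- marking_system(nm)
    pd <- phenotype_distribution(sys)
    expect_true(all(is_canonical_phenotype(sys, pd$phenotype)$canonical),
                info = nm)
  }
})

test_that("chromatid oracle: exhaustive enumeration matches Monte Carlo", {
  sys <- marking_system("GFPNEG_FRT19A")
  asm <- segregation_assumptions()
  ex <- chromatid_oracle(sys, asm, "exhaustive")
  expect_equal(sum(ex$probability), 1, tolerance = 1e-12)
  # uniform pairing + random segregation gives 1/4 homozygous-loss
  # daughters (one recombinant chromatid per homolog, picked w.p. 1/2 each)
  expect_equal(ex$probability[ex$phenotype == "GFP-"], 0.25,
               tolerance = 1e-12)

  n <- 1e5
  mc <- chromatid_oracle(sys, asm, "monte_carlo", n = n, seed = 11)
  p_mc <- mc$probability[mc$phenotype == "GFP-"]
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(p_mc - 0.25), 3 * se)
  # total-variation convergence at n = 1e5
  tv <- sum(abs(
    mc$probability[match(ex$phenotype, mc$phenotype)] - ex$probability)) / 2
  expect_lt(tv, 0.01)

  expect_error(chromatid_oracle(sys, asm, "monte_carlo", n = 0),
               "positive count")
})

test_that("chromatid oracle reproduces the equal-genotype model on demand", {
  lgr <- marking_system("LGR")
  eq <- chromatid_oracle(
    lgr, segregation_assumptions(segregation = "equal_genotype"))
  pd <- phenotype_distribution(lgr)
  expect_equal(eq$probability[match(pd$phenotype, eq$phenotype)],
               pd$probability, tolerance = 1e-12)
  # under mechanistic chromatid segregation the distribution differs
  mech <- chromatid_oracle(lgr, segregation_assumptions(), "exhaustive")
  expect_equal(sum(mech$probability), 1, tolerance = 1e-12)
  expect_gt(mech$probability[mech$phenotype == "BGR"], 2 / 9)
  # X segregation sends the two exchanged chromatids to opposite
  # daughters, so every daughter of a single-FRT exchange is homo- or
  # heterozygous in equal measure
  xseg <- chromatid_oracle(
    marking_system("GFPNEG_FRT19A"),
    segregation_assumptions(segregation = "recombinants_apart"),
    "exhaustive")
  expect_equal(xseg$probability[xseg$phenotype == "GFP-"], 0.5,
               tolerance = 1e-12)
})
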