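toyMedium <- function(...) {
  fl <- c(...)
  methods::new("DietFluxes", fluxes = fl,
               provenance = stats::setNames(rep("food", length(fl)),
                                            names(fl)),
               unitState = "per-hour")
}

test_that("community FBA solves the hand-checked single-taxon LP", {
  # yield 0.5 gDW/mmol, 10 mmol/h substrate -> mu_max = 5
  m <- makeToyTaxon("Solo", "G", yield = 0.5)
  cm <- assembleCommunity(list(m), abundanceProfile(c(Solo = 1)))
  sol <- maximizeCommunityGrowth(cm, toyMedium(G = 10))
  expect_equal(sol@status, "optimal")
  expect_equal(sol@muCMax, 5, tolerance = 1e-7)
  expect_equal(sol@alpha, 1)
  # empty medium: nothing to eat
  sol0 <- maximizeCommunityGrowth(cm, toyMedium(G = 0))
  expect_equal(sol0@muCMax, 0, tolerance = 1e-7)
  # LP scaling: doubling the medium doubles the optimum
  sol2 <- maximizeCommunityGrowth(cm, toyMedium(G = 20))
  expect_equal(sol2@muCMax, 2 * sol@muCMax, tolerance = 1e-6)
})

test_that("cooperative trade-off reproduces the closed-form allocation", {
  # two taxa growing 1:1 on a shared substrate, a = (0.6, 0.4), alpha 0.5:
  # mu_i = 0.5 * 10 * a_i / (a'a) = (5.769231, 3.846154)
  com <- sharedSubstrateCommunity(1, ntax = 2, yield = 1, supply = 10)
  a <- c(0.6, 0.4)
  prof <- abundanceProfile(stats::setNames(a, c("T1", "T2")))
  cm <- assembleCommunity(com$model@models, prof)
  sol <- cooperativeTradeoff(cm, com$medium, alpha = 0.5)
  expect_equal(unname(growthRates(sol)), 0.5 * 10 * a / sum(a^2),
               tolerance = 1e-6)
  expect_equal(unname(growthRates(sol)), c(5.769231, 3.846154),
               tolerance = 1e-5)
  # alpha = 1 disables the trade-off
  sol1 <- cooperativeTradeoff(cm, com$medium, alpha = 1)
  expect_equal(sol1@muC, sol1@muCMax, tolerance = 1e-6)
  # single taxon: mu = alpha * muCmax for any alpha
  solo <- makeToyTaxon("Solo", "G", yield = 0.5)
  cms <- assembleCommunity(list(solo), abundanceProfile(c(Solo = 1)))
  ss <- cooperativeTradeoff(cms, toyMedium(G = 10), alpha = 0.3)
  expect_equal(unname(growthRates(ss)), 0.3 * 5, tolerance = 1e-6)
})

test_that("trade-off allocations match the active-set QP oracle", {
  # exclusive substrates with unequal capacity: caps bind for some taxa
  mA <- makeToyTaxon("A", "SA", yield = 0.5)
  mB <- makeToyTaxon("B", "SB", yield = 0.4)
  prof <- abundanceProfile(c(A = 0.7, B = 0.3))
  cm <- assembleCommunity(list(mA, mB), prof)
  med <- toyMedium(SA = 10, SB = 0.4)
  step1 <- maximizeCommunityGrowth(cm, med)
  a <- c(0.7, 0.3)
  cap <- c(0.5 * 10, 0.4 * 0.4) / a      # per-taxon growth capacity
  for (alpha in c(0.9, 0.6, 0.3)) {
    sol <- cooperativeTradeoff(cm, med, alpha = alpha)
    oracle <- muAllocOracle(a, alpha * step1@muCMax, cap)
    expect_equal(unname(growthRates(sol)), oracle, tolerance = 1e-5)
  }
})

test_that("optimal-alpha search picks the largest alpha growing most taxa", {
  # B's substrate is scarce and shared with A; at alpha = 1 the allocation
  # starves the low-efficiency taxon, lower alphas let it grow
  mA <- makeToyTaxon("A", "S", yield = 0.5)
  mB <- makeToyTaxon("B", "S", yield = 0.2)
  prof <- abundanceProfile(c(A = 0.8, B = 0.2))
  cm <- assembleCommunity(list(mA, mB), prof)
  med <- toyMedium(S = 10)
  sol <- findOptimalAlpha(cm, med)
  # independent exhaustive scan over the same grid
  counts <- vapply(seq(1, 0.1, by = -0.1), function(alpha) {
    s <- cooperativeTradeoff(cm, med, alpha = alpha)
    sum(growthRates(s) > 1e-6)
  }, numeric(1))
  grid <- seq(1, 0.1, by = -0.1)
  expect_equal(sol@alpha, grid[which.max(counts)])
  expect_equal(sum(growthRates(sol) > 1e-6), max(counts))
  # early exit: scan stops once every taxon grows
  expect_lte(nrow(sol@trace), which.max(counts))
})

test_that("alpha scan trace covers the whole grid when taxa never grow", {
  # taxon with zero-yield substrate can never grow: no early exit
  mA <- makeToyTaxon("A", "S", yield = 0.5)
  mB <- genTaxon(archetypeSpec("generalist",
    list(S2 = list(yield = 1e-9, products = c()))), "B")
  prof <- abundanceProfile(c(A = 0.8, B = 0.2))
  cm <- assembleCommunity(list(mA, mB), prof)
  sol <- findOptimalAlpha(cm, toyMedium(S = 10, S2 = 1))
  expect_equal(nrow(sol@trace), 10L)
  expect_equal(sol@trace$alpha, seq(1, 0.1, by = -0.1))
})

test_that("solution validation reports residuals and trade-off respect", {
  m <- makeToyTaxon("Solo", "G", yield = 0.5)
  cm <- assembleCommunity(list(m), abundanceProfile(c(Solo = 1)))
  sol <- maximizeCommunityGrowth(cm, toyMedium(G = 10))
  chk <- checkSolution(cm, sol)
  expect_lt(chk$maxResidual, 1e-6)
  expect_equal(chk$muCResidual, 0)
  expect_true(chk$tradeoffRespected)
  # a near-zero growth rate counts as negligible (threshold 1e-6)
  sol@mu[1] <- 1e-9
  attr(sol@mu, "abundances") <- cm@abundances
  sol@muC <- sum(cm@abundances * sol@mu)
  chk2 <- checkSolution(cm, sol)
  expect_equal(chk2$nNegligible, 1L)
  expect_false(chk2$tradeoffRespected)
  # perturbing one flux moves the residual by at least the matching
  # stoichiometric column magnitude
  solp <- maximizeCommunityGrowth(cm, toyMedium(G = 10))
  j <- cm@biomassColumns[[1]]
  solp@fluxes[j] <- solp@fluxes[j] + 1
  colmax <- max(abs(as.numeric(cm@S[, j])))
  expect_gte(checkSolution(cm, solp)$maxResidual, colmax - 1e-6)
})

test_that("identical inputs give identical solutions", {
  com <- randomToyCommunity(99)
  s1 <- findOptimalAlpha(com$model, com$medium)
  s2 <- findOptimalAlpha(com$model, com$medium)
  expect_identical(s1@fluxes, s2@fluxes)
  expect_identical(growthRates(s1), growthRates(s2))
})

test_that("maximal community growth is monotone in the diet", {
  for (seed in c(3, 4, 5)) {
    com <- randomToyCommunity(seed)
    base <- maximizeCommunityGrowth(com$model, com$medium)
    richer <- com$medium
    richer@fluxes <- richer@fluxes * 1.7
    more <- maximizeCommunityGrowth(com$model, richer)
    expect_gte(more@muCMax + 1e-7, base@muCMax)
  }
})

test_that("allocations shrink proportionally to abundance as alpha drops", {
  com <- sharedSubstrateCommunity(5, ntax = 3, yield = 1, supply = 12)
  a <- com$abundances
  for (alpha in c(0.2, 0.05)) {
    sol <- cooperativeTradeoff(com$model, com$medium, alpha = alpha)
    cf <- alpha * sol@muCMax * a / sum(a^2)
    expect_equal(growthRates(sol), cf, tolerance = 1e-5)
  }
})

test_that("solutions serialise to JSON and fluxes to TSV", {
  m <- makeToyTaxon("Solo", "G", yield = 0.5, products = c(P = 1))
  cm <- assembleCommunity(list(m), abundanceProfile(c(Solo = 1)))
  sol <- maximizeCommunityGrowth(cm, toyMedium(G = 10))
  jp <- tempfile(fileext = ".json")
  writeSolutionJSON(sol, cm, jp)
  doc <- jsonlite::read_json(jp)
  expect_equal(doc$mu_c, sol@muC, tolerance = 1e-12)
  expect_equal(doc$status, "optimal")
  tp <- tempfile(fileext = ".tsv")
  writeFluxesTSV(sol, cm, tp)
  tab <- utils::read.delim(tp)
  expect_equal(nrow(tab), ncol(cm@S))
  expect_equal(tab$flux, unname(sol@fluxes), tolerance = 1e-9)
})
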