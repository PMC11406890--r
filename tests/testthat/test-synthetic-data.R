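test_that("generated archetypes obey their stoichiometry under FBA", {
  spec <- archetypeSpec("acetogen",
    list(G = list(yield = 0.5, products = c(acetate = 2))))
  m <- genTaxon(spec, "Ace")
  cm <- assembleCommunity(list(m), abundanceProfile(c(Ace = 1)))
  med <- methods::new("DietFluxes", fluxes = c(G = 10),
                      provenance = c(G = "food"), unitState = "per-hour")
  sol <- maximizeCommunityGrowth(cm, med)
  expect_equal(sol@muCMax, 0.5 * 10, tolerance = 1e-6)
  expect_equal(aggregateMetaboliteFlux(cm, sol, "acetate"), 2 * 10,
               tolerance = 1e-5)
  # identical calls give identical models
  expect_identical(
    as.matrix(stoichiometry(genTaxon(spec, "Ace", seed = 1))),
    as.matrix(stoichiometry(genTaxon(spec, "Ace", seed = 1))))
})

test_that("cofactor requirements starve taxa until completion", {
  m <- genTaxon(archetypeSpec("generalist",
    list(G = list(yield = 0.5, products = c())),
    cofactors = c(V = 0.1)), "Needy")
  med <- methods::new("DietFluxes", fluxes = c(G = 10),
                      provenance = c(G = "food"), unitState = "per-hour")
  expect_equal(weanflux:::.singleTaxonGrowth(m, med), 0, tolerance = 1e-8)
  done <- suppressMessages(completeMedium(list(m), med, 0.01))
  expect_gte(weanflux:::.singleTaxonGrowth(m, done), 0.01 - 1e-9)
})

test_that("food tables have the promised structure", {
  # n = 1: only breastmilk
  t1 <- readFoodTable(genFoodTable(1, seed = 5))
  expect_identical(names(t1), "breastmilk")
  tab <- readFoodTable(genFoodTable(14, seed = 5))
  expect_true(all(c("breastmilk", "infant_formula") %in% names(tab)))
  # infant formula matches breastmilk per kcal
  milk <- tab$breastmilk
  form <- tab$infant_formula
  expect_equal(form@composition / form@energyDensity,
               milk@composition / milk@energyDensity, tolerance = 1e-12)
  # fibre-rich plant groups carry more non-absorbable saccharide per gram
  # than animal proteins
  nonabs <- function(f) sum(f@composition[!f@absorbable &
    grepl("fiber|hmo|gos", names(f@composition))])
  fruit <- tab[[which(vapply(tab, function(f) f@groupLabel,
                             character(1)) == "fruit")[1]]]
  meat <- tab[[which(vapply(tab, function(f) f@groupLabel,
                            character(1)) == "animal-protein")[1]]]
  expect_gt(nonabs(fruit), nonabs(meat))
  # fixed seed: byte-identical CSV
  p1 <- genFoodTable(14, seed = 5)
  p2 <- genFoodTable(14, seed = 5)
  expect_identical(readLines(p1), readLines(p2))
  # different seed: different jitter
  p3 <- genFoodTable(14, seed = 6)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("scenarios exercise the abundance filter as designed", {
  sc <- suppressMessages(genScenario(nTaxa = 10, nFoods = 3, seed = 2))
  prof <- loadAbundances(sc$abundanceFile)
  expect_equal(length(abundances(prof)), 11L)     # one sub-1% genus on top
  filtered <- suppressMessages(filterAbundances(prof, 0.01))
  expect_equal(length(abundances(filtered)), 10L)
  expect_false("Escherichia" %in% names(abundances(filtered)))
  expect_setequal(names(abundances(filtered)), names(sc$models))
  # every generated food has ground-truth entries for both panels
  foods <- setdiff(names(sc$foods), c("breastmilk", "infant_formula"))
  for (f in foods) {
    sub <- sc$groundTruth[sc$groundTruth$food_1 == f &
                            is.na(sc$groundTruth$food_2), ]
    expect_setequal(sub$panel, c("total_scfa", "total_bcfa"))
  }
})

test_that("screen results are invariant to food-table order", {
  sc <- suppressMessages(genScenario(nTaxa = 4, nFoods = 2, seed = 4))
  prof <- renormalizeProfile(suppressMessages(filterAbundances(
    loadAbundances(sc$abundanceFile))))
  keep <- names(abundances(prof)) %in% names(sc$models)
  cm <- assembleCommunity(sc$models, prof)
  cfg <- screenConfig()
  res1 <- suppressWarnings(suppressMessages(
    runScreen(sc$foods, cm, config = cfg)))
  res2 <- suppressWarnings(suppressMessages(
    runScreen(rev(sc$foods), cm, config = cfg)))
  ids1 <- vapply(res1, function(r) r@combinationId, character(1))
  ids2 <- vapply(res2, function(r) r@combinationId, character(1))
  expect_setequal(ids1, ids2)
  for (id in ids1) {
    r1 <- res1[[match(id, ids1)]]
    r2 <- res2[[match(id, ids2)]]
    expect_equal(r1@metaboliteFluxes, r2@metaboliteFluxes, tolerance = 1e-9)
    expect_identical(r1@classification, r2@classification)
  }
})
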