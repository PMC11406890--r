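# small two-taxon screen world used across these tests
screenWorld <- function() {
  mA <- genTaxon(archetypeSpec("acetogen",
    list(lactose = list(yield = 0.5, products = c(acetate = 1.5)))), "Ace")
  mB <- genTaxon(archetypeSpec("proteolytic-bcfa",
    list(protein = list(yield = 0.3,
                        products = c(isovalerate = 0.5,
                                     isobutyrate = 0.25)))), "Bcf")
  prof <- abundanceProfile(c(Ace = 0.7, Bcf = 0.3))
  cm <- assembleCommunity(list(mA, mB), prof)
  foods <- list(
    breastmilk = foodItem("breastmilk", "milk", 0.65,
      c(lactose = 0.20, protein = 0.02),
      c(lactose = TRUE, protein = TRUE)),
    fiberfruit = foodItem("fiberfruit", "fruit", 0.55,
      c(lactose = 0.30, protein = 0.001),
      c(lactose = TRUE, protein = TRUE)),
    meat = foodItem("meat", "animal-protein", 1.9,
      c(protein = 0.25), c(protein = TRUE)))
  list(cm = cm, foods = foods)
}

test_that("metabolite aggregation weights per-taxon secretion", {
  mA <- makeToyTaxon("A", "SA", yield = 1, products = c(P = 2))
  mB <- makeToyTaxon("B", "SB", yield = 1, products = c(P = 2))
  prof <- abundanceProfile(c(A = 0.6, B = 0.4))
  cm <- assembleCommunity(list(mA, mB), prof)
  sol <- maximizeCommunityGrowth(cm, methods::new("DietFluxes",
    fluxes = c(SA = 5, SB = 5), provenance = c(SA = "food", SB = "food"),
    unitState = "per-hour"))
  # A secretes 2*5/0.6 per gDW, B 2*5/0.4: weighted sum = 2*5 + 2*5 = 20
  expect_equal(aggregateMetaboliteFlux(cm, sol, "P"), 20, tolerance = 1e-6)
  # hand-woven solution: secretions (10, 5) with a = (0.6, 0.4) -> 8
  info <- cm@reactionInfo
  sel <- which(info$type == "exchange" & info$metabolite == "P")
  sol@fluxes[sel] <- c(10, 5)
  expect_equal(aggregateMetaboliteFlux(cm, sol, "P"), 8)
  # all-zero fluxes aggregate to zero
  sol@fluxes[] <- 0
  expect_equal(aggregateMetaboliteFlux(cm, sol, "P"), 0)
  expect_error(aggregateMetaboliteFlux(cm, sol, "unobtainium"),
               "missing-compound")
  # single taxon, abundance 1: aggregation is the taxon's own secretion
  cm1 <- assembleCommunity(list(mA), abundanceProfile(c(A = 1)))
  sol1 <- maximizeCommunityGrowth(cm1, methods::new("DietFluxes",
    fluxes = c(SA = 5), provenance = c(SA = "food"), unitState = "per-hour"))
  ex1 <- which(cm1@reactionInfo$type == "exchange" &
                 cm1@reactionInfo$metabolite == "P")
  expect_equal(aggregateMetaboliteFlux(cm1, sol1, "P"),
               unname(sol1@fluxes[ex1]), tolerance = 1e-9)
})

test_that("producer aggregation clips consumers, net mode does not", {
  mA <- makeToyTaxon("A", "SA", yield = 1, products = c(P = 2))
  mB <- makeToyTaxon("B", "SB", yield = 1, products = c(P = 2))
  cm <- assembleCommunity(list(mA, mB), abundanceProfile(c(A = 0.5, B = 0.5)))
  sol <- maximizeCommunityGrowth(cm, methods::new("DietFluxes",
    fluxes = c(SA = 1, SB = 1), provenance = c(SA = "food", SB = "food"),
    unitState = "per-hour"))
  sel <- which(cm@reactionInfo$type == "exchange" &
                 cm@reactionInfo$metabolite == "P")
  sol@fluxes[sel] <- c(10, -4)
  expect_equal(aggregateMetaboliteFlux(cm, sol, "P", "producers"), 5)
  expect_equal(aggregateMetaboliteFlux(cm, sol, "P", "net"), 3)
})

test_that("panel totals sum only their members", {
  fl <- c(acetate = 6, propionate = 2, butyrate = 1, isovalerate = 0.3)
  tot <- panelTotals(fl)
  expect_equal(unname(tot), c(9, 0.3))
  expect_equal(unname(panelTotals(numeric())), c(0, 0))
  # non-panel compounds are ignored
  expect_equal(panelTotals(c(fl, lactate = 5)), tot)
})

test_that("relative variation and classification behave at the edges", {
  expect_equal(relativeVariation(11.17, 10), 11.7, tolerance = 1e-9)
  expect_equal(relativeVariation(10, 10), 0)
  expect_equal(relativeVariation(0, 10), -100)
  expect_true(is.na(relativeVariation(5, 0)))
  expect_equal(classifyCombination(6.4), "increase")
  expect_equal(classifyCombination(0.5), "no-change")
  expect_equal(classifyCombination(-40.2), "decrease")
  expect_equal(classifyCombination(1.0), "no-change")  # band is inclusive
  expect_error(classifyCombination(NA_real_), "undefined")
})

test_that("the screen classifies foods by their engineered effect", {
  w <- screenWorld()
  cfg <- screenConfig(solver = solverConfig())
  res <- suppressWarnings(suppressMessages(
    runScreen(w$foods, w$cm, config = cfg)))
  ids <- vapply(res, function(r) r@combinationId, character(1))
  expect_setequal(ids, c("breastmilk", "fiberfruit+breastmilk",
                         "meat+breastmilk"))
  byid <- stats::setNames(res, ids)
  # control identity: milk-only has zero relative variation throughout
  ctrl <- byid[["breastmilk"]]
  expect_true(all(abs(ctrl@relVariation) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(ctrl@growthRelVariation) < 1e-9, na.rm = TRUE))
  # the sugar-rich fruit raises total SCFA, the meat raises total BCFA
  expect_equal(byid[["fiberfruit+breastmilk"]]@classification[["total_scfa"]],
               "increase")
  expect_equal(byid[["meat+breastmilk"]]@classification[["total_bcfa"]],
               "increase")
  expect_equal(byid[["meat+breastmilk"]]@classification[["total_scfa"]],
               "decrease")
  # results come sorted by total SCFA, descending
  scfa <- vapply(res, function(r) r@totalSCFA, numeric(1))
  expect_equal(scfa, sort(scfa, decreasing = TRUE))
})

test_that("combination bookkeeping matches the pair combinatorics", {
  w <- screenWorld()
  foods12 <- c(list(breastmilk = w$foods$breastmilk),
               lapply(seq_len(12), function(i)
                 foodItem(paste0("f", i), "test", 1, c(lactose = 0.1),
                          c(lactose = TRUE))))
  names(foods12)[-1] <- paste0("f", 1:12)
  pairs <- allFoodPairs(foods12, exclude = "breastmilk")
  expect_equal(nrow(pairs), 66)            # C(12, 2)
  designs <- weanflux:::.combinationDesigns(foods12, pairs, screenConfig())
  expect_equal(length(designs), 1 + 12 + 66)
  # screen with no complementary foods: control-only output
  res <- suppressWarnings(suppressMessages(runScreen(
    list(breastmilk = w$foods$breastmilk), w$cm, config = screenConfig())))
  expect_equal(length(res), 1L)
  expect_equal(res[[1]]@combinationId, "breastmilk")
})

test_that("reports export, render NA, and reload losslessly", {
  w <- screenWorld()
  res <- suppressWarnings(suppressMessages(
    runScreen(w$foods, w$cm, config = screenConfig())))
  dir <- tempfile("report")
  files <- exportReport(res, dir)
  tab <- utils::read.delim(files[["tsv"]], check.names = FALSE)
  expect_equal(nrow(tab), length(res))
  expect_true(any(is.na(tab[, -1])))       # undefined cells render as NA
  back <- readScreenResults(files[["json"]])
  for (i in seq_along(res)) {
    expect_identical(back[[i]]@combinationId, res[[i]]@combinationId)
    expect_equal(back[[i]]@relVariation, res[[i]]@relVariation)
    expect_equal(back[[i]]@metaboliteFluxes, res[[i]]@metaboliteFluxes)
    expect_identical(back[[i]]@classification, res[[i]]@classification)
  }
  expect_error(exportReport(list(), tempfile()), "nonempty")
})

test_that("screen configuration reads from YAML", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "totalEnergy: 500",
    "milkFraction: 0.8",
    "noChangeBand: 2",
    "aggregate: net",
    "solver:",
    "  negligibleGrowth: 1.0e-5",
    "  alphaGrid: [1.0, 0.5]"), yml)
  cfg <- readScreenConfig(yml)
  expect_equal(cfg$totalEnergy, 500)
  expect_equal(cfg$milkFraction, 0.8)
  expect_equal(cfg$noChangeBand, 2)
  expect_equal(cfg$aggregate, "net")
  expect_equal(cfg$solver$negligibleGrowth, 1e-5)
  expect_equal(cfg$solver$alphaGrid, c(1, 0.5))
})
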