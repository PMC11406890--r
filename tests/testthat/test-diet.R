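milkFood <- function() foodItem("breastmilk", "milk", 0.65,
                                c(lactose = 0.2, protein = 0.02),
                                c(lactose = TRUE, protein = TRUE))

test_that("diet construction follows the caloric arithmetic", {
  foods <- list(
    breastmilk = milkFood(),
    lentils = foodItem("lentils", "legume", 1.2,
                       c(fiber = 0.1, protein = 0.06)))
  design <- dietDesign(c(breastmilk = 0.85, lentils = 0.15), 608)
  diet <- buildDiet(design, foods)
  # milk mass = 0.85 * 608 / 0.65 g/day
  milk_g <- 0.85 * 608 / 0.65
  expect_equal(milk_g, 795.0769, tolerance = 1e-6)
  expect_equal(dietFluxes(diet)[["lactose"]], milk_g * 0.2, tolerance = 1e-9)
  lent_g <- 0.15 * 608 / 1.2
  expect_equal(dietFluxes(diet)[["fiber"]], lent_g * 0.1, tolerance = 1e-9)
  expect_equal(dietFluxes(diet)[["protein"]],
               milk_g * 0.02 + lent_g * 0.06, tolerance = 1e-9)
  expect_equal(unitState(diet), "per-day")
  expect_true(all(provenance(diet) == "food"))
})

test_that("single-component and pair designs are energy-consistent", {
  f <- foodItem("x", "test", 1, c(X = 2))
  diet <- buildDiet(dietDesign(c(x = 1), 100), list(x = f))
  expect_equal(dietFluxes(diet)[["X"]], 200)   # 100 g * 2 mmol/g
  # two-food design: equal fractions and equal energy densities give equal
  # masses, each half of the single-food mass
  fa <- foodItem("a", "test", 2, c(X = 1))
  fb <- foodItem("b", "test", 2, c(Y = 1))
  milk <- milkFood()
  foods <- list(a = fa, b = fb, breastmilk = milk)
  pair <- buildDiet(dietDesign(c(a = 0.075, b = 0.075, breastmilk = 0.85),
                               608), foods)
  single <- buildDiet(dietDesign(c(a = 0.15, breastmilk = 0.85), 608), foods)
  expect_equal(dietFluxes(pair)[["X"]], dietFluxes(pair)[["Y"]])
  expect_equal(dietFluxes(pair)[["X"]], dietFluxes(single)[["X"]] / 2,
               tolerance = 1e-12)
  expect_error(buildDiet(dietDesign(c(nothere = 1), 100), foods),
               "missing-food")
})

test_that("unit conversion divides by 24 exactly and refuses to repeat", {
  d <- methods::new("DietFluxes", fluxes = c(X = 240),
                    provenance = c(X = "food"), unitState = "per-day")
  h <- convertToHourly(d)
  expect_identical(dietFluxes(h)[["X"]], 10)
  expect_equal(unitState(h), "per-hour")
  expect_error(convertToHourly(h), "already per-hour")
  empty <- methods::new("DietFluxes", fluxes = numeric(),
                        provenance = character(), unitState = "per-day")
  expect_equal(length(dietFluxes(convertToHourly(empty))), 0L)
})

test_that("absorption attenuates exactly the flagged compounds", {
  d <- methods::new("DietFluxes", fluxes = c(glucose = 50, fiber = 30),
                    provenance = c(glucose = "food", fiber = "food"),
                    unitState = "per-hour")
  out <- applyAbsorption(d, "glucose", 0.2)
  expect_equal(dietFluxes(out), c(glucose = 10, fiber = 30))
  expect_identical(provenance(out), provenance(d))
  # empty set and unit factor are identities
  expect_equal(dietFluxes(applyAbsorption(d, character())), dietFluxes(d))
  expect_equal(dietFluxes(applyAbsorption(d, "glucose", 1)), dietFluxes(d))
  # absorbed compound missing from the diet is logged, not an error
  expect_message(applyAbsorption(d, c("glucose", "starch")), "starch")
})

test_that("host secretions add at 1 mmol/h with provenance", {
  empty <- methods::new("DietFluxes", fluxes = numeric(),
                        provenance = character(), unitState = "per-hour")
  out <- addHostSecretions(empty)
  expect_equal(dietFluxes(out),
               c(mucin_core = 1, glycocholate = 1, taurocholate = 1))
  expect_true(all(provenance(out) == "host-secretion"))
  # additivity when the compound is already present
  d <- methods::new("DietFluxes", fluxes = c(mucin_core = 0.5),
                    provenance = c(mucin_core = "food"),
                    unitState = "per-hour")
  expect_equal(dietFluxes(addHostSecretions(d))[["mucin_core"]], 1.5)
  # empty secretions: identity
  expect_equal(dietFluxes(addHostSecretions(d, numeric())), dietFluxes(d))
  expect_error(addHostSecretions(d, c(mucin_core = -1)), "negative")
  # secretions must not intersect the absorbed set
  expect_error(addHostSecretions(d, absorbed = "mucin_core"),
               "absorbed")
  # per-day diets are refused
  dd <- methods::new("DietFluxes", fluxes = c(X = 1),
                     provenance = c(X = "food"), unitState = "per-day")
  expect_error(addHostSecretions(dd), "mmol/h")
})

test_that("food tables and diet JSON round-trip", {
  path <- genFoodTable(4, seed = 3)
  foods <- readFoodTable(path)
  expect_true("breastmilk" %in% names(foods))
  diet <- buildDiet(dietDesign(c(breastmilk = 1), 608), foods)
  diet <- convertToHourly(diet)
  jp <- tempfile(fileext = ".json")
  writeDietJSON(diet, jp)
  back <- readDietJSON(jp)
  expect_identical(dietFluxes(back), dietFluxes(diet))
  expect_identical(provenance(back), provenance(diet))
  expect_identical(unitState(back), unitState(diet))
})
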