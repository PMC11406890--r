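#' Archetype specification for a toy taxon reconstruction
#'
#' A fermentation archetype: one or more substrates, each with a biomass
#' yield (gDW per mmol) and a product stoichiometry (mmol product per mmol
#' substrate), plus optional cofactor requirements (mmol per gDW of
#' biomass).  Archetypes emulate the metabolic roles behind colonic
#' organic-acid production: saccharolytic acetogens, propionogens and
#' butyrogens, and proteolytic producers of branched-chain fatty acids.
#'
#' @param archetype label: acetogen, propionogen, butyrogen,
#'   proteolytic-bcfa or generalist.
#' @param substrates named list; each element is
#'   \code{list(yield = <gDW/mmol>, products = c(compound = mmol/mmol))}.
#' @param cofactors named numeric, mmol required per gDW of biomass.
#' @return an \code{ArchetypeSpec} list.
#' @export
archetypeSpec <- function(archetype, substrates, cofactors = numeric()) {
  stopifnot(length(substrates) >= 1,
            all(vapply(substrates, function(s) s$yield > 0, logical(1))))
  structure(list(archetype = archetype, substrates = substrates,
                 cofactors = cofactors), class = "ArchetypeSpec")
}

#' Generate a toy taxon reconstruction from an archetype
#'
#' Builds, per substrate, an uptake/secretion exchange and a catabolic
#' reaction converting one mmol of substrate into \code{yield} gDW of
#' biomass precursor plus the archetype's products; products leave through
#' secretion-only exchanges, cofactors enter through uptake exchanges and
#' are consumed by the biomass reaction, which is normalised to produce
#' 1 g dry weight per unit flux (so biomass flux is the growth rate in
#' 1/h).  Construction is fully deterministic; \code{seed} is accepted for
#' interface symmetry with the other generators but draws nothing.
#'
#' @param spec an [archetypeSpec()].
#' @param taxonId taxon (genus) identifier.
#' @param seed unused; generation is deterministic.
#' @param reversibleProducts compounds whose product exchange should also
#'   allow uptake (enables cross-feeding scenarios).
#' @return a \linkS4class{TaxonModel}.
#' @export
genTaxon <- function(spec, taxonId, seed = 0L, reversibleProducts = character()) {
  stopifnot(inherits(spec, "ArchetypeSpec"))
  subs <- names(spec$substrates)
  prods <- unique(unlist(lapply(spec$substrates, function(s) names(s$products))))
  cofs <- names(spec$cofactors)
  lumen <- c(subs, prods, cofs)
  mets <- rbind(
    data.frame(id = lumen, name = lumen, compartment = LUMEN_COMPARTMENT,
               stringsAsFactors = FALSE),
    data.frame(id = paste0(c(subs, prods, cofs), "_c"),
               name = c(subs, prods, cofs), compartment = taxonId,
               stringsAsFactors = FALSE),
    data.frame(id = "biomass_pre", name = "biomass precursor",
               compartment = taxonId, stringsAsFactors = FALSE))
  rxns <- list()
  for (s in subs) {
    rxns[[paste0("EX_", s)]] <- list(
      id = paste0("EX_", s),
      stoich = stats::setNames(c(1, -1), c(s, paste0(s, "_c"))),
      kind = "exchange", lb = -1000, ub = 1000)
    st <- stats::setNames(c(-1, spec$substrates[[s]]$yield),
                          c(paste0(s, "_c"), "biomass_pre"))
    pr <- spec$substrates[[s]]$products
    if (length(pr))
      st <- c(st, stats::setNames(as.numeric(pr), paste0(names(pr), "_c")))
    rxns[[paste0("CAT_", s)]] <- list(
      id = paste0("CAT_", s), stoich = st, kind = "internal",
      lb = 0, ub = 1000)
  }
  for (p in prods) {
    rxns[[paste0("EX_", p)]] <- list(
      id = paste0("EX_", p),
      stoich = stats::setNames(c(1, -1), c(p, paste0(p, "_c"))),
      kind = "exchange",
      lb = if (p %in% reversibleProducts) -1000 else 0, ub = 1000)
  }
  for (cf in cofs) {
    rxns[[paste0("EX_", cf)]] <- list(
      id = paste0("EX_", cf),
      stoich = stats::setNames(c(1, -1), c(cf, paste0(cf, "_c"))),
      kind = "exchange", lb = -1000, ub = 1000)
  }
  bm <- stats::setNames(-1, "biomass_pre")
  if (length(cofs))
    bm <- c(bm, stats::setNames(-as.numeric(spec$cofactors), paste0(cofs, "_c")))
  rxns[["BIOMASS"]] <- list(id = "BIOMASS", stoich = bm, kind = "biomass",
                            lb = 0, ub = 1000)
  taxonModel(taxonId, mets, unname(rxns))
}

# the default 10-genus archetype community plus one sub-1% genus without a
# reconstruction (exercises the abundance filter the way real genus tables
# do); abundances mix high (>10%) and low (1-3%) members
.communityArchetypes <- function() {
  list(
    Bifidobacterium = list(abundance = 0.25, spec = archetypeSpec("acetogen",
      list(lactose = list(yield = 0.50, products = c(acetate = 1.5)),
           hmo = list(yield = 0.45, products = c(acetate = 1.2))))),
    Bacteroides = list(abundance = 0.20, spec = archetypeSpec("propionogen",
      list(fiber_pectin = list(yield = 0.45,
                               products = c(propionate = 1.0, acetate = 0.5))))),
    Bacillus = list(abundance = 0.15, spec = archetypeSpec("generalist",
      list(glucose = list(yield = 0.50, products = c(acetate = 1.0))))),
    Clostridium = list(abundance = 0.10, spec = archetypeSpec("butyrogen",
      list(fiber_starch = list(yield = 0.40,
                               products = c(butyrate = 0.8, acetate = 0.3))))),
    Prevotella = list(abundance = 0.08, spec = archetypeSpec("propionogen",
      list(fiber_xylan = list(yield = 0.42,
                              products = c(propionate = 0.9, acetate = 0.4))))),
    Veillonella = list(abundance = 0.06, spec = archetypeSpec("generalist",
      list(mucin_core = list(yield = 0.35,
                             products = c(acetate = 0.6, propionate = 0.4))),
      cofactors = c(vit_b1 = 0.05))),
    Collinsella = list(abundance = 0.05, spec = archetypeSpec("acetogen",
      list(gos = list(yield = 0.40, products = c(acetate = 1.0))),
      cofactors = c(vit_b2 = 0.08))),
    Lactobacillus = list(abundance = 0.04, spec = archetypeSpec("generalist",
      list(glucose = list(yield = 0.50, products = c(acetate = 1.0))))),
    Streptococcus = list(abundance = 0.025, spec = archetypeSpec("proteolytic-bcfa",
      list(protein_aa = list(yield = 0.35,
                             products = c(isovalerate = 0.45, isobutyrate = 0.30,
                                          acetate = 0.20))))),
    Lacticaseibacillus = list(abundance = 0.015, spec = archetypeSpec("proteolytic-bcfa",
      list(protein_aa2 = list(yield = 0.30,
                              products = c(isovalerate = 0.50,
                                           isobutyrate = 0.25)))))
  )
}

.unmodeledGenus <- function() c(Escherichia = 0.006)

.absorbableCompounds <- function() {
  c(lactose = TRUE, glucose = TRUE, protein_aa = TRUE, protein_aa2 = TRUE,
    lipid = TRUE,
    hmo = FALSE, gos = FALSE, fiber_pectin = FALSE, fiber_xylan = FALSE,
    fiber_starch = FALSE, mucin_core = FALSE, glycocholate = FALSE,
    taurocholate = FALSE, vit_b1 = FALSE, vit_b2 = FALSE)
}

# complementary-food templates: group-typical compositions (mmol/g); plant
# foods carry non-absorbable fibres, animal proteins carry amino acids
.foodTemplates <- function() {
  list(
    fruit_berry_1 = list(group = "fruit", ed = 0.55,
      comp = c(glucose = 0.10, fiber_pectin = 0.07, fiber_xylan = 0.010)),
    fruit_berry_2 = list(group = "fruit", ed = 0.50,
      comp = c(glucose = 0.09, fiber_pectin = 0.06, fiber_xylan = 0.015)),
    fruit_pome_1 = list(group = "fruit", ed = 0.60,
      comp = c(glucose = 0.12, fiber_pectin = 0.05)),
    veg_squash_1 = list(group = "vegetable", ed = 0.30,
      comp = c(glucose = 0.04, fiber_pectin = 0.06, fiber_starch = 0.05)),
    veg_root_1 = list(group = "vegetable", ed = 0.90,
      comp = c(glucose = 0.05, fiber_starch = 0.12, fiber_pectin = 0.03)),
    veg_leafy_1 = list(group = "vegetable", ed = 0.25,
      comp = c(glucose = 0.02, fiber_pectin = 0.05, fiber_xylan = 0.04)),
    cereal_wheat_1 = list(group = "cereal", ed = 3.6,
      comp = c(fiber_starch = 0.30, fiber_xylan = 0.20, protein_aa = 0.04)),
    cereal_oat_1 = list(group = "cereal", ed = 3.8,
      comp = c(fiber_starch = 0.35, fiber_xylan = 0.12, protein_aa = 0.05)),
    legume_bean_1 = list(group = "legume", ed = 1.3,
      comp = c(fiber_starch = 0.15, protein_aa = 0.08, fiber_pectin = 0.04)),
    legume_pea_1 = list(group = "legume", ed = 1.2,
      comp = c(fiber_starch = 0.12, protein_aa = 0.07, protein_aa2 = 0.03,
               fiber_pectin = 0.05)),
    meat_poultry_1 = list(group = "animal-protein", ed = 1.9,
      comp = c(protein_aa = 0.25, protein_aa2 = 0.15, lipid = 0.05)),
    fish_white_1 = list(group = "animal-protein", ed = 1.1,
      comp = c(protein_aa = 0.22, protein_aa2 = 0.18, lipid = 0.03))
  )
}

.breastmilkComposition <- function() {
  list(group = "milk", ed = 0.65,
       comp = c(lactose = 0.20, hmo = 0.010, gos = 0.005, protein_aa = 0.020,
                protein_aa2 = 0.010, glucose = 0.005, lipid = 0.004))
}

#' Generate a synthetic food composition table
#'
#' Deterministic given \code{seed}.  The first item is always a
#' breastmilk-like food (lactose, oligosaccharides, protein, lipid mix);
#' the second an infant formula matching breastmilk per kcal (so it makes
#' a clean second control); further items cycle through group templates
#' (fruits, vegetables, cereals, legumes, animal proteins) with a +/-5\%
#' multiplicative jitter on compound contents.  Fibre-rich plant groups
#' carry more non-absorbable saccharide per gram than the animal-protein
#' group by template construction.
#'
#' @param nFoods total number of items including breastmilk (and, for
#'   \code{nFoods >= 2}, infant formula).
#' @param seed integer RNG seed.
#' @param path output CSV path.
#' @return \code{path}, invisibly; the CSV is in [readFoodTable()] format.
#' @export
genFoodTable <- function(nFoods = 14, seed = 7,
                         path = tempfile(fileext = ".csv")) {
  stopifnot(nFoods >= 1)
  absorb <- .absorbableCompounds()
  milk <- .breastmilkComposition()
  items <- list(breastmilk = milk)
  if (nFoods >= 2) {
    f_ed <- 0.67
    items$infant_formula <- list(group = "formula", ed = f_ed,
                                 comp = milk$comp * (f_ed / milk$ed))
  }
  if (nFoods >= 3) {
    templates <- .foodTemplates()
    set.seed(seed)
    for (k in seq_len(nFoods - 2)) {
      tpl <- templates[[(k - 1) %% length(templates) + 1]]
      id <- names(templates)[(k - 1) %% length(templates) + 1]
      if (k > length(templates)) id <- paste0(id, "_v", (k - 1) %/% length(templates))
      jit <- 1 + 0.1 * (stats::runif(length(tpl$comp)) - 0.5)
      items[[id]] <- list(group = tpl$group, ed = tpl$ed, comp = tpl$comp * jit)
    }
  }
  rows <- do.call(rbind, lapply(names(items), function(id) {
    it <- items[[id]]
    data.frame(food_id = id, group = it$group,
               energy_density_kcal_per_g = it$ed,
               compound = names(it$comp),
               mmol_per_g = as.numeric(it$comp),
               absorbable = unname(absorb[names(it$comp)]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(format(rows, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- analytic ground truth ------------------------------------------------
# Expected community metabolite totals for a diet design, derived directly
# from archetype stoichiometry and the diet arithmetic, independent of the
# LP/QP machinery: substrate-limited taxa convert their full substrate
# supply; cofactor-capped taxa contribute the constant flux implied by the
# minimally completed cofactor supply.

.gtDietFluxes <- function(fractions, foods_df, totalEnergy = 608,
                          absorptionFactor = 0.2,
                          secretions = defaultHostSecretions()) {
  flux <- numeric(0)
  for (fid in names(fractions)) {
    ft <- foods_df[foods_df$food_id == fid, ]
    grams <- fractions[[fid]] * totalEnergy / ft$energy_density_kcal_per_g[1]
    for (i in seq_len(nrow(ft))) {
      cpd <- ft$compound[i]
      flux[cpd] <- (if (cpd %in% names(flux)) flux[[cpd]] else 0) +
        grams * ft$mmol_per_g[i]
    }
  }
  flux <- flux / 24
  ab <- .absorbableCompounds()
  hit <- names(flux)[ab[names(flux)] %in% TRUE]
  flux[hit] <- flux[hit] * absorptionFactor
  for (cpd in names(secretions))
    flux[cpd] <- (if (cpd %in% names(flux)) flux[[cpd]] else 0) + secretions[[cpd]]
  flux
}

.gtCompletedFluxes <- function(diet, arch, minGrowth = 0.01) {
  sup <- numeric(0)
  bump <- function(sup, cpd, val) {
    sup[cpd] <- max(if (cpd %in% names(sup)) sup[[cpd]] else 0, val)
    sup
  }
  for (tx in names(arch)) {
    spec <- arch[[tx]]$spec
    for (cf in names(spec$cofactors)) {
      have <- if (cf %in% names(diet)) diet[[cf]] else 0
      need <- minGrowth * spec$cofactors[[cf]]
      if (have < need) sup <- bump(sup, cf, need - have)
    }
    # single-taxon growth on food-derived substrates; minimal completion
    # tops up the highest-yield substrate when the floor is unreachable
    yields <- vapply(spec$substrates, `[[`, numeric(1), "yield")
    ds <- vapply(names(spec$substrates), function(s)
      if (s %in% names(diet)) diet[[s]] else 0, numeric(1))
    g <- sum(yields * ds)
    if (g < minGrowth) {
      best <- which.max(yields)
      sup <- bump(sup, names(spec$substrates)[best],
                  (minGrowth - g) / yields[best])
    }
  }
  for (cpd in names(sup))
    diet[cpd] <- (if (cpd %in% names(diet)) diet[[cpd]] else 0) + sup[[cpd]]
  diet
}

.gtTotals <- function(diet, arch, abund, minGrowth = 0.01) {
  totals <- numeric(0)
  add <- function(totals, cpd, val) {
    totals[cpd] <- (if (cpd %in% names(totals)) totals[[cpd]] else 0) + val
    totals
  }
  for (tx in names(arch)) {
    spec <- arch[[tx]]$spec
    a <- abund[[tx]]
    if (length(spec$cofactors)) {
      # cofactor-capped: community growth contribution a*mu is limited by
      # the minimally completed cofactor supply to minGrowth
      s <- names(spec$substrates)[1]
      y <- spec$substrates[[1]]$yield
      ds <- if (s %in% names(diet)) diet[[s]] else 0
      cap_cof <- min(vapply(names(spec$cofactors), function(cf)
        diet[[cf]] / spec$cofactors[[cf]], numeric(1)))
      amu <- min(cap_cof, y * ds)            # = a * mu
      up <- amu / y                          # community substrate uptake
      for (p in names(spec$substrates[[1]]$products))
        totals <- add(totals, p, spec$substrates[[1]]$products[[p]] * up)
    } else {
      for (s in names(spec$substrates)) {
        ds <- if (s %in% names(diet)) diet[[s]] else 0
        share <- .gtSubstrateShare(arch, abund, tx, s)
        for (p in names(spec$substrates[[s]]$products))
          totals <- add(totals, p,
                        spec$substrates[[s]]$products[[p]] * ds * share)
      }
    }
  }
  totals
}

# substrate shared by several substrate-limited taxa with identical
# parameters is fully consumed collectively; attribute it once
.gtSubstrateShare <- function(arch, abund, taxon, substrate) {
  consumers <- names(arch)[vapply(names(arch), function(tx)
    substrate %in% names(arch[[tx]]$spec$substrates) &&
      !length(arch[[tx]]$spec$cofactors), logical(1))]
  if (taxon == consumers[1]) 1 else 0
}

#' Generate a complete synthetic scenario with ground truth
#'
#' Produces toy genus reconstructions, a genus abundance table (mixing
#' high >10\% and low 1--3\% abundances, plus one sub-1\% genus without a
#' reconstruction, so the 1\% filter has work to do), a food table, and
#' the analytically derived expected screening direction
#' (increase/decrease/no-change of total SCFA and total BCFA versus the
#' milk-only control) for every single-food and pair combination.
#' Everything is deterministic given \code{seed}.
#'
#' The expected directions come from the archetype stoichiometry alone:
#' substrate-limited taxa convert their entire substrate supply at the
#' optimal trade-off, so community metabolite totals are linear in the
#' completed diet fluxes; cofactor-limited taxa contribute the constant
#' production implied by minimal medium completion.  No LP/QP is solved.
#'
#' @param nTaxa number of modeled taxa (2--10); the sub-1\% genus is
#'   added on top.
#' @param nFoods number of complementary foods (the food table adds
#'   breastmilk and infant formula).
#' @param seed integer seed.
#' @param dir directory for the abundance TSV and food CSV.
#' @param crossFeeding also allow the butyrogen to consume acetate
#'   (default off; ground truth is only generated for the default).
#' @return list with \code{models} (list of \linkS4class{TaxonModel}),
#'   \code{abundanceFile}, \code{foodFile}, \code{foods},
#'   \code{groundTruth} (data.frame: combination_id, food_1, food_2,
#'   panel, expected, expected_rel), and \code{seed}.
#' @export
genScenario <- function(nTaxa = 10, nFoods = 12, seed = 7,
                        dir = tempfile("scenario"), crossFeeding = FALSE) {
  stopifnot(nTaxa >= 2, nTaxa <= 10, nFoods >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arch <- .communityArchetypes()[seq_len(nTaxa)]
  models <- lapply(names(arch), function(tx)
    genTaxon(arch[[tx]]$spec, tx, seed,
             reversibleProducts = if (crossFeeding && tx == "Clostridium")
               "acetate" else character()))
  names(models) <- names(arch)
  ab <- c(vapply(arch, `[[`, numeric(1), "abundance"), .unmodeledGenus())
  ab_file <- file.path(dir, "abundances.tsv")
  utils::write.table(data.frame(taxon = names(ab), abundance = ab),
                     ab_file, sep = "\t", quote = FALSE, row.names = FALSE)
  food_file <- file.path(dir, "foods.csv")
  genFoodTable(nFoods + 2, seed, food_file)
  foods_df <- utils::read.csv(food_file, stringsAsFactors = FALSE)
  foods <- readFoodTable(food_file)

  retained <- vapply(arch, `[[`, numeric(1), "abundance")
  retained <- retained / sum(retained)        # post-filter renormalisation
  panel <- metabolitePanel()
  complementary <- setdiff(names(foods), c("breastmilk", "infant_formula"))
  designs <- list()
  designs[["infant_formula"]] <- c(infant_formula = 1)
  for (f in complementary)
    designs[[paste(f, "breastmilk", sep = "+")]] <-
      stats::setNames(c(0.15, 0.85), c(f, "breastmilk"))
  if (length(complementary) >= 2) {
    prs <- utils::combn(complementary, 2)
    for (i in seq_len(ncol(prs)))
      designs[[paste(prs[1, i], prs[2, i], "breastmilk", sep = "+")]] <-
        stats::setNames(c(0.075, 0.075, 0.85),
                        c(prs[1, i], prs[2, i], "breastmilk"))
  }
  gtFor <- function(fractions) {
    d <- .gtCompletedFluxes(.gtDietFluxes(fractions, foods_df), arch)
    tot <- .gtTotals(d, arch, retained)
    panelTotals(tot, panel)
  }
  ctrl <- gtFor(c(breastmilk = 1))
  gt <- do.call(rbind, lapply(names(designs), function(id) {
    tot <- gtFor(designs[[id]])
    fr <- names(designs[[id]])
    fr <- fr[fr != "breastmilk"]
    do.call(rbind, lapply(c("total_scfa", "total_bcfa"), function(p) {
      rel <- if (ctrl[[p]] > 0) 100 * (tot[[p]] - ctrl[[p]]) / ctrl[[p]]
             else NA_real_
      data.frame(combination_id = id,
                 food_1 = fr[1], food_2 = if (length(fr) > 1) fr[2] else NA,
                 panel = p,
                 expected = if (is.finite(rel)) classifyCombination(rel, 1.0)
                            else NA_character_,
                 expected_rel = rel, stringsAsFactors = FALSE)
    }))
  }))
  list(models = models, abundanceFile = ab_file, foodFile = food_file,
       foods = foods, groundTruth = gt, seed = seed,
       crossFeeding = crossFeeding)
}
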