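#' Construct a food item
#'
#' @param foodId identifier.
#' @param groupLabel food group (fruit, vegetable, legume, cereal,
#'   animal-protein, milk, ...).
#' @param energyDensity kcal per gram (> 0).
#' @param composition named numeric, compound content in mmol per gram.
#' @param absorbable named logical flags, parallel to \code{composition}:
#'   \code{TRUE} for compounds absorbed in the small intestine (their
#'   colonic flux is attenuated by [applyAbsorption()]).
#' @return a \linkS4class{FoodItem}.
#' @export
foodItem <- function(foodId, groupLabel, energyDensity, composition,
                     absorbable = NULL) {
  if (is.null(absorbable))
    absorbable <- stats::setNames(rep(FALSE, length(composition)),
                                  names(composition))
  methods::new("FoodItem", foodId = foodId, groupLabel = groupLabel,
               energyDensity = energyDensity, composition = composition,
               absorbable = absorbable[names(composition)])
}

#' Read a food composition table
#'
#' Long-format CSV with columns \code{food_id}, \code{group},
#' \code{energy_density_kcal_per_g}, \code{compound}, \code{mmol_per_g},
#' \code{absorbable} -- the shape exported by diet-design tools.  The
#' absorbable flag must be consistent for a compound across all foods.
#'
#' @param path CSV file path.
#' @return named list of \linkS4class{FoodItem}.
#' @export
readFoodTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("food_id", "group", "energy_density_kcal_per_g", "compound",
            "mmol_per_g", "absorbable")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("food table lacks column(s): ", paste(miss, collapse = ", "))
  flag <- tapply(as.logical(tab$absorbable), tab$compound,
                 function(x) length(unique(x)))
  if (any(flag > 1))
    stop("inconsistent absorbable flag for compound(s): ",
         paste(names(flag)[flag > 1], collapse = ", "))
  out <- lapply(split(tab, tab$food_id), function(ft) {
    ed <- unique(ft$energy_density_kcal_per_g)
    grp <- unique(ft$group)
    if (length(ed) != 1 || length(grp) != 1)
      stop("food '", ft$food_id[1],
           "' has inconsistent energy density or group")
    foodItem(ft$food_id[1], grp, ed,
             stats::setNames(ft$mmol_per_g, ft$compound),
             stats::setNames(as.logical(ft$absorbable), ft$compound))
  })
  out[order(names(out))]
}

#' Absorbed-compound set of a food table
#'
#' @param foods named list of \linkS4class{FoodItem}.
#' @return character vector of compounds flagged absorbable.
#' @export
absorbedCompounds <- function(foods) {
  sort(unique(unlist(lapply(foods, function(f)
    names(f@composition)[f@absorbable]))))
}

#' Describe a diet as a caloric mix of foods
#'
#' @param components named numeric of caloric fractions (names are food
#'   ids; fractions sum to 1), e.g. \code{c(breastmilk = 0.85,
#'   lentils = 0.15)}.
#' @param totalEnergy total intake in kcal per day; the default 608
#'   corresponds to a 6-month-old infant's daily energy requirement.
#' @return a \linkS4class{DietDesign}.
#' @export
dietDesign <- function(components, totalEnergy = 608) {
  methods::new("DietDesign",
               components = data.frame(food_id = names(components),
                                       caloric_fraction = as.numeric(components),
                                       stringsAsFactors = FALSE),
               totalEnergy = totalEnergy)
}

#' Build diet compound fluxes from a design
#'
#' For each component food, the consumed mass is
#' \code{grams = fraction * totalEnergy / energyDensity}; compound fluxes
#' are the mass-weighted sums of the composition tables, in mmol per day
#' (\code{unitState = "per-day"}).  The recomputed energy of the mix
#' equals the design total within 1e-6 kcal by construction, which is
#' asserted.
#'
#' @param design a \linkS4class{DietDesign}.
#' @param foods named list of \linkS4class{FoodItem} covering every
#'   component.
#' @return a per-day \linkS4class{DietFluxes} with provenance
#'   \code{"food"}.
#' @export
buildDiet <- function(design, foods) {
  stopifnot(methods::is(design, "DietDesign"))
  methods::validObject(design)
  cmp <- design@components
  miss <- setdiff(cmp$food_id, names(foods))
  if (length(miss))
    stop("missing-food error: ", paste(miss, collapse = ", "))
  flux <- numeric(0)
  energy <- 0
  for (i in seq_len(nrow(cmp))) {
    f <- foods[[cmp$food_id[i]]]
    if (f@energyDensity <= 0) stop("validation error: zero energy density")
    grams <- cmp$caloric_fraction[i] * design@totalEnergy / f@energyDensity
    energy <- energy + grams * f@energyDensity
    for (cpd in names(f@composition)) {
      flux[cpd] <- (if (cpd %in% names(flux)) flux[[cpd]] else 0) +
        grams * f@composition[[cpd]]
    }
  }
  stopifnot(abs(energy - design@totalEnergy) < 1e-6)
  flux <- flux[flux > 0]
  methods::new("DietFluxes", fluxes = flux,
               provenance = stats::setNames(rep("food", length(flux)),
                                            names(flux)),
               unitState = "per-day")
}

#' Convert diet fluxes from per-day to per-hour
#'
#' Divides every flux by 24.  Calling it on fluxes already in per-hour
#' units is an error, guarding against double conversion.
#'
#' @param diet a per-day \linkS4class{DietFluxes}.
#' @return the per-hour \linkS4class{DietFluxes}.
#' @export
convertToHourly <- function(diet) {
  stopifnot(methods::is(diet, "DietFluxes"))
  if (diet@unitState != "per-day")
    stop("idempotency error: diet fluxes are already per-hour")
  methods::new("DietFluxes", fluxes = diet@fluxes / 24,
               provenance = diet@provenance, unitState = "per-hour")
}

#' Attenuate absorbed compounds
#'
#' Multiplies the flux of every compound in \code{absorbed} by
#' \code{factor} (default 0.2), accounting for small-intestinal absorption
#' before the digesta reaches the colon.  Compounds not in the set (e.g.
#' non-digestible fibres) pass through untouched.  Absorbed compounds
#' missing from the diet are logged and ignored.
#'
#' @param diet a \linkS4class{DietFluxes}.
#' @param absorbed character vector of compound ids.
#' @param factor fraction of the ingested flux that escapes absorption,
#'   in (0, 1].
#' @return the adjusted \linkS4class{DietFluxes}.
#' @export
applyAbsorption <- function(diet, absorbed, factor = 0.2) {
  stopifnot(methods::is(diet, "DietFluxes"), factor > 0, factor <= 1)
  fl <- diet@fluxes
  hit <- intersect(absorbed, names(fl))
  missed <- setdiff(absorbed, names(fl))
  if (length(missed))
    message("applyAbsorption: compound(s) not in diet, ignored: ",
            paste(missed, collapse = ", "))
  fl[hit] <- fl[hit] * factor
  methods::new("DietFluxes", fluxes = fl, provenance = diet@provenance,
               unitState = diet@unitState)
}

#' Default host secretions
#'
#' Mucin cores and the bile acids glycocholate and taurocholate, each at
#' 1 mmol/h: the host-derived substrates available to colonic microbes
#' independent of diet.
#'
#' @return named numeric (mmol/h).
#' @export
defaultHostSecretions <- function() {
  c("mucin_core" = 1, "glycocholate" = 1, "taurocholate" = 1)
}

#' Add host-secreted compounds to the diet
#'
#' Adds each secretion flux to the (per-hour) diet, summing when the
#' compound is already present, with provenance \code{"host-secretion"}.
#' Secretion compounds must not overlap the absorbed-compound set: host
#' secretions enter the lumen distal to the small intestine, so applying
#' the absorption factor to them would be wrong, and the non-overlap makes
#' [applyAbsorption()] and this step order-independent.
#'
#' @param diet a per-hour \linkS4class{DietFluxes}.
#' @param secretions named numeric of fluxes in mmol/h; default
#'   [defaultHostSecretions()].
#' @param absorbed optional absorbed-compound set to validate the
#'   non-overlap against.
#' @return the augmented \linkS4class{DietFluxes}.
#' @export
addHostSecretions <- function(diet, secretions = defaultHostSecretions(),
                              absorbed = character()) {
  stopifnot(methods::is(diet, "DietFluxes"))
  if (diet@unitState != "per-hour")
    stop("host secretions are specified in mmol/h; convert the diet first")
  if (any(secretions < 0))
    stop("validation error: negative secretion flux")
  bad <- intersect(names(secretions), absorbed)
  if (length(bad))
    stop("secretion compound(s) must not be in the absorbed set: ",
         paste(bad, collapse = ", "))
  fl <- diet@fluxes; pv <- diet@provenance
  for (cpd in names(secretions)) {
    fl[cpd] <- (if (cpd %in% names(fl)) fl[[cpd]] else 0) + secretions[[cpd]]
    pv[cpd] <- "host-secretion"
  }
  methods::new("DietFluxes", fluxes = fl, provenance = pv[names(fl)],
               unitState = "per-hour")
}

#' Serialise / reload diet fluxes
#'
#' Bit-exact JSON round trip of fluxes, provenance and unit state.
#'
#' @param diet a \linkS4class{DietFluxes}.
#' @param path JSON file path.
#' @return \code{path} (write) or the reloaded \linkS4class{DietFluxes}
#'   (read).
#' @export
writeDietJSON <- function(diet, path) {
  jsonlite::write_json(
    list(unit_state = diet@unitState,
         fluxes = as.list(diet@fluxes),
         provenance = as.list(diet@provenance)),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname writeDietJSON
#' @export
readDietJSON <- function(path) {
  doc <- jsonlite::read_json(path)
  methods::new("DietFluxes",
               fluxes = unlist(doc$fluxes),
               provenance = unlist(doc$provenance),
               unitState = doc$unit_state)
}
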