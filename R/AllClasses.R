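#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t crossprod rowSums colSums
NULL

LUMEN_COMPARTMENT <- "shared-lumen"
EXTERNAL_COMPARTMENT <- "external"

#' Taxon-level metabolic reconstruction
#'
#' Container for one genus (or strain) metabolic reconstruction: a set of
#' metabolites, a set of reactions with flux bounds, the stoichiometric
#' matrix linking them, and the identity of the biomass reaction.  The
#' biomass reaction is normalised so that unit flux produces 1 g dry weight
#' of biomass; its flux is therefore the growth rate in 1/h.
#'
#' Metabolite compartments are either the taxon's own identifier (internal
#' metabolites), \code{"shared-lumen"} (metabolites exchanged with the
#' common gut lumen) or \code{"external"}.  Exchange reactions are the only
#' reactions allowed to touch a shared-lumen or external metabolite, and
#' each touches exactly one such metabolite; by convention positive
#' exchange flux is secretion into the lumen and negative flux is uptake.
#'
#' @slot taxonId character(1), genus identifier.
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}.
#' @slot reactions data.frame with columns \code{id}, \code{kind}
#'   (\code{internal}, \code{exchange} or \code{biomass}), \code{lb},
#'   \code{ub} (mmol/(gDW h)).
#' @slot stoichiometry sparse \code{Matrix} (metabolites x reactions).
#' @slot biomassId character(1), reaction id of the biomass reaction.
#'
#' @exportClass TaxonModel
setClass("TaxonModel",
  representation(
    taxonId = "character",
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    biomassId = "character"
  )
)

.validTaxonModel <- function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  if (!all(c("id", "name", "compartment") %in% names(met)))
    msg <- c(msg, "metabolites must have columns id, name, compartment")
  if (!all(c("id", "kind", "lb", "ub") %in% names(rxn)))
    msg <- c(msg, "reactions must have columns id, kind, lb, ub")
  if (length(msg)) return(msg)
  if (anyDuplicated(met$id))
    msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id))
    msg <- c(msg, "duplicated reaction ids")
  if (any(rxn$lb > rxn$ub + 1e-12))
    msg <- c(msg, "reaction with lower_bound > upper_bound")
  if (!all(rxn$kind %in% c("internal", "exchange", "biomass")))
    msg <- c(msg, "reaction kind must be internal, exchange or biomass")
  nbm <- sum(rxn$kind == "biomass")
  if (nbm != 1L)
    msg <- c(msg, sprintf("exactly one biomass reaction required (found %d)", nbm))
  if (length(object@biomassId) != 1L ||
      !identical(object@biomassId, rxn$id[rxn$kind == "biomass"][1]))
    msg <- c(msg, "biomassId must name the unique biomass reaction")
  S <- object@stoichiometry
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msg <- c(msg, "stoichiometry dimensions do not match metabolites/reactions")
  bad_comp <- !(met$compartment %in%
                  c(object@taxonId, LUMEN_COMPARTMENT, EXTERNAL_COMPARTMENT))
  if (any(bad_comp))
    msg <- c(msg, paste0("internal metabolite compartment must name the taxon: ",
                         paste(met$id[bad_comp], collapse = ", ")))
  if (!length(msg) && nrow(rxn)) {
    boundary <- met$compartment %in% c(LUMEN_COMPARTMENT, EXTERNAL_COMPARTMENT)
    for (j in which(rxn$kind == "exchange")) {
      touched <- which(S[, j] != 0)
      if (sum(boundary[touched]) != 1L)
        msg <- c(msg, sprintf(
          "exchange reaction '%s' must touch exactly one shared-lumen/external metabolite",
          rxn$id[j]))
    }
    for (j in which(rxn$kind == "internal")) {
      touched <- which(S[, j] != 0)
      if (any(boundary[touched]))
        msg <- c(msg, sprintf(
          "internal reaction '%s' touches a shared-lumen/external metabolite",
          rxn$id[j]))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("TaxonModel", .validTaxonModel)

#' Genus relative-abundance profile
#'
#' Named vector of relative abundances (fractions summing to at most 1;
#' exactly 1 after \code{\link{renormalizeProfile}}).  The \code{info} slot
#' carries bookkeeping from filtering (retained count and mass).
#'
#' @slot abundances named numeric, one entry per taxon, all > 0.
#' @slot sourceLabel character(1) describing provenance.
#' @slot info list of bookkeeping values.
#' @exportClass AbundanceProfile
setClass("AbundanceProfile",
  representation(
    abundances = "numeric",
    sourceLabel = "character",
    info = "list"
  ),
  prototype(info = list())
)

setValidity("AbundanceProfile", function(object) {
  a <- object@abundances
  msg <- character()
  if (is.null(names(a)) || any(!nzchar(names(a))))
    msg <- c(msg, "abundances must be named by taxon")
  if (anyDuplicated(names(a)))
    msg <- c(msg, "duplicated taxon in abundance profile")
  if (any(!is.finite(a)) || any(a <= 0))
    msg <- c(msg, "all abundances must be finite and > 0")
  if (length(a) && sum(a) > 1 + 1e-9)
    msg <- c(msg, "abundances sum to more than 1")
  if (length(msg)) msg else TRUE
})

#' Abundance-weighted community metabolic model
#'
#' Block stoichiometric matrix over all taxa plus the shared lumen.  Each
#' taxon keeps its own rows for internal metabolites; shared-lumen
#' metabolites get a single community row in which taxon exchange fluxes
#' enter scaled by the taxon's relative abundance.  One diet exchange
#' column per lumen metabolite exports from the lumen (coefficient -1);
#' its lower bound is set to minus the diet flux at solve time, so uptake
#' by the community appears as negative diet-exchange flux bounded by the
#' medium.
#'
#' @slot taxa character vector of taxon ids (in block order).
#' @slot abundances named numeric, relative abundances (sum 1).
#' @slot models list of \code{TaxonModel}, parallel to \code{taxa}.
#' @slot S sparse community stoichiometric matrix.
#' @slot lb,ub numeric flux bounds per column.
#' @slot reactionInfo data.frame: \code{id} (community column id),
#'   \code{taxon} (\code{NA} for diet columns), \code{type}
#'   (internal/exchange/biomass/diet), \code{metabolite} (lumen metabolite
#'   for exchange/diet columns, else \code{NA}).
#' @slot metaboliteInfo data.frame: \code{id}, \code{taxon} (\code{NA} for
#'   lumen rows), \code{compartment}.
#' @slot biomassColumns named integer, taxon -> column index.
#' @slot dietColumns named integer, lumen metabolite -> column index.
#' @exportClass CommunityModel
setClass("CommunityModel",
  representation(
    taxa = "character",
    abundances = "numeric",
    models = "list",
    S = "Matrix",
    lb = "numeric",
    ub = "numeric",
    reactionInfo = "data.frame",
    metaboliteInfo = "data.frame",
    biomassColumns = "integer",
    dietColumns = "integer"
  )
)

setValidity("CommunityModel", function(object) {
  msg <- character()
  if (length(object@taxa) != length(object@models) ||
      length(object@taxa) != length(object@abundances))
    msg <- c(msg, "taxa, models and abundances must be parallel")
  if (abs(sum(object@abundances) - 1) > 1e-6)
    msg <- c(msg, "community abundances must sum to 1 (renormalize first)")
  if (length(object@biomassColumns) != length(object@taxa))
    msg <- c(msg, "one biomass column per taxon required")
  if (ncol(object@S) != length(object@lb) || ncol(object@S) != length(object@ub))
    msg <- c(msg, "bounds must match the number of columns")
  if (nrow(object@reactionInfo) != ncol(object@S))
    msg <- c(msg, "reactionInfo must describe every column")
  if (length(msg)) msg else TRUE
})

#' Diet flux vector (medium)
#'
#' Named non-negative fluxes of lumen compounds, with provenance flags
#' (\code{food}, \code{host-secretion}, \code{completion-supplement}) and a
#' unit state (\code{per-day} straight from food tables, \code{per-hour}
#' after \code{\link{convertToHourly}}; solving requires per-hour).
#'
#' @slot fluxes named numeric, all >= 0.
#' @slot provenance named character, parallel to \code{fluxes}.
#' @slot unitState \code{"per-day"} or \code{"per-hour"}.
#' @exportClass DietFluxes
setClass("DietFluxes",
  representation(
    fluxes = "numeric",
    provenance = "character",
    unitState = "character"
  )
)

setValidity("DietFluxes", function(object) {
  msg <- character()
  f <- object@fluxes
  if (length(f) && (is.null(names(f)) || anyDuplicated(names(f))))
    msg <- c(msg, "fluxes must be uniquely named by compound")
  if (any(!is.finite(f)) || any(f < -1e-12))
    msg <- c(msg, "diet fluxes must be finite and non-negative")
  if (!identical(names(object@provenance), names(f)))
    msg <- c(msg, "provenance must be parallel to fluxes")
  if (!object@unitState %in% c("per-day", "per-hour"))
    msg <- c(msg, "unitState must be per-day or per-hour")
  if (length(msg)) msg else TRUE
})

#' Cooperative trade-off solution
#'
#' Result of community FBA with (or without) the cooperative trade-off:
#' community growth rate, per-taxon growth rates, the full flux vector and
#' solver bookkeeping.  \code{status} is one of \code{optimal},
#' \code{infeasible}, \code{numerically-unstable}.
#'
#' @slot muC community growth rate (1/h), the abundance-weighted sum of
#'   per-taxon growth rates.
#' @slot muCMax maximal community growth rate from step 1 (1/h).
#' @slot mu named numeric, per-taxon growth rates (1/h).
#' @slot alpha trade-off fraction in (0, 1].
#' @slot fluxes named numeric, flux per community column (mmol/(gDW h)).
#' @slot status character(1).
#' @slot trace data.frame with the alpha-scan trace (may be empty).
#' @exportClass TradeoffSolution
setClass("TradeoffSolution",
  representation(
    muC = "numeric",
    muCMax = "numeric",
    mu = "numeric",
    alpha = "numeric",
    fluxes = "numeric",
    status = "character",
    trace = "data.frame"
  ),
  prototype(trace = data.frame())
)

setValidity("TradeoffSolution", function(object) {
  msg <- character()
  if (!object@status %in% c("optimal", "infeasible", "numerically-unstable"))
    msg <- c(msg, "unknown solver status")
  if (object@status == "optimal") {
    if (any(object@mu < -1e-6))
      msg <- c(msg, "negative growth rate in optimal solution")
    if (abs(object@muC - sum(.solutionWeights(object) * object@mu)) > 1e-8)
      msg <- c(msg, "muC must equal the abundance-weighted sum of mu")
  }
  if (length(msg)) msg else TRUE
})

# weights recovered from attributes set at construction time
.solutionWeights <- function(sol) {
  w <- attr(sol@mu, "abundances")
  if (is.null(w)) rep(1, length(sol@mu)) else w
}

#' Food item
#'
#' One food from a composition table: energy density plus compound content
#' per gram, with per-compound absorbability flags (absorbable compounds
#' are attenuated in the small intestine before reaching the colon).
#'
#' @slot foodId character(1).
#' @slot groupLabel character(1) (e.g. fruit, legume, animal-protein).
#' @slot energyDensity kcal per gram, > 0.
#' @slot composition named numeric, mmol per gram, >= 0.
#' @slot absorbable named logical, parallel to \code{composition}.
#' @exportClass FoodItem
setClass("FoodItem",
  representation(
    foodId = "character",
    groupLabel = "character",
    energyDensity = "numeric",
    composition = "numeric",
    absorbable = "logical"
  )
)

setValidity("FoodItem", function(object) {
  msg <- character()
  if (!is.finite(object@energyDensity) || object@energyDensity <= 0)
    msg <- c(msg, "energy density must be > 0")
  if (any(object@composition < 0))
    msg <- c(msg, "composition values must be >= 0")
  if (!identical(names(object@absorbable), names(object@composition)))
    msg <- c(msg, "absorbable flags must be parallel to composition")
  if (length(msg)) msg else TRUE
})

#' Diet design (caloric mix of foods)
#'
#' @slot components data.frame with columns \code{food_id} and
#'   \code{caloric_fraction} (fractions sum to 1).
#' @slot totalEnergy kcal per day.
#' @exportClass DietDesign
setClass("DietDesign",
  representation(components = "data.frame", totalEnergy = "numeric")
)

setValidity("DietDesign", function(object) {
  msg <- character()
  cmp <- object@components
  if (!all(c("food_id", "caloric_fraction") %in% names(cmp)))
    msg <- c(msg, "components needs food_id and caloric_fraction columns")
  else {
    if (any(cmp$caloric_fraction < 0))
      msg <- c(msg, "caloric fractions must be >= 0")
    if (abs(sum(cmp$caloric_fraction) - 1) > 1e-9)
      msg <- c(msg, "caloric fractions must sum to 1")
  }
  if (!is.finite(object@totalEnergy) || object@totalEnergy <= 0)
    msg <- c(msg, "total energy must be > 0")
  if (length(msg)) msg else TRUE
})

#' Screen result for one food-breastmilk combination
#'
#' @slot combinationId character(1).
#' @slot metaboliteFluxes named numeric, aggregated community secretion
#'   flux per compound (mmol/(gDW h)).
#' @slot totalSCFA,totalBCFA numeric(1) panel totals.
#' @slot relVariation named numeric, percent change vs the milk-only
#'   control per compound and panel (NA where the control flux is 0).
#' @slot growthRelVariation named numeric, percent change of per-taxon
#'   growth rates vs control.
#' @slot classification named character, increase/decrease/no-change per
#'   panel.
#' @slot alphaUsed numeric(1).
#' @slot solverStatus character(1).
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(
    combinationId = "character",
    metaboliteFluxes = "numeric",
    totalSCFA = "numeric",
    totalBCFA = "numeric",
    relVariation = "numeric",
    growthRelVariation = "numeric",
    classification = "character",
    alphaUsed = "numeric",
    solverStatus = "character"
  )
)
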