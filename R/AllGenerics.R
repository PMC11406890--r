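#' @include AllClasses.R
NULL

#' Accessors for weanflux classes
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x an object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxonId", function(x) standardGeneric("taxonId"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setGeneric("biomassId", function(x) standardGeneric("biomassId"))
#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("dietFluxes", function(x) standardGeneric("dietFluxes"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("unitState", function(x) standardGeneric("unitState"))
#' @rdname accessors
#' @export
setGeneric("growthRates", function(x) standardGeneric("growthRates"))
#' @rdname accessors
#' @export
setGeneric("communityGrowth", function(x) standardGeneric("communityGrowth"))
#' @rdname accessors
#' @export
setGeneric("solutionFluxes", function(x) standardGeneric("solutionFluxes"))
#' @rdname accessors
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @rdname accessors
#' @export
setMethod("taxonId", "TaxonModel", function(x) x@taxonId)
#' @rdname accessors
#' @export
setMethod("reactions", "TaxonModel", function(x) x@reactions)
#' @rdname accessors
#' @export
setMethod("metabolites", "TaxonModel", function(x) x@metabolites)
#' @rdname accessors
#' @export
setMethod("stoichiometry", "TaxonModel", function(x) x@stoichiometry)
#' @rdname accessors
#' @export
setMethod("biomassId", "TaxonModel", function(x) x@biomassId)

#' @rdname accessors
#' @export
setMethod("abundances", "AbundanceProfile", function(x) x@abundances)
#' @rdname accessors
#' @export
setMethod("abundances", "CommunityModel", function(x) x@abundances)
#' @rdname accessors
#' @export
setMethod("stoichiometry", "CommunityModel", function(x) x@S)
#' @rdname accessors
#' @export
setMethod("taxonId", "CommunityModel", function(x) x@taxa)

#' @rdname accessors
#' @export
setMethod("dietFluxes", "DietFluxes", function(x) x@fluxes)
#' @rdname accessors
#' @export
setMethod("provenance", "DietFluxes", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("unitState", "DietFluxes", function(x) x@unitState)

#' @rdname accessors
#' @export
setMethod("growthRates", "TradeoffSolution", function(x) {
  mu <- x@mu
  attr(mu, "abundances") <- NULL
  mu
})
#' @rdname accessors
#' @export
setMethod("communityGrowth", "TradeoffSolution", function(x) x@muC)
#' @rdname accessors
#' @export
setMethod("solutionFluxes", "TradeoffSolution", function(x) x@fluxes)
#' @rdname accessors
#' @export
setMethod("solverStatus", "TradeoffSolution", function(x) x@status)

setMethod("show", "TaxonModel", function(object) {
  rx <- object@reactions
  cat("TaxonModel:", object@taxonId, "\n",
      " ", nrow(object@metabolites), "metabolites,",
      nrow(rx), "reactions (",
      sum(rx$kind == "internal"), "internal,",
      sum(rx$kind == "exchange"), "exchange, biomass:",
      object@biomassId, ")\n")
})

setMethod("show", "AbundanceProfile", function(object) {
  a <- object@abundances
  cat("AbundanceProfile [", object@sourceLabel, "]: ",
      length(a), " taxa, total mass ", format(sum(a), digits = 6), "\n", sep = "")
  head_n <- utils::head(sort(a, decreasing = TRUE), 5)
  for (i in seq_along(head_n))
    cat(sprintf("  %-24s %.4f\n", names(head_n)[i], head_n[i]))
  if (length(a) > 5) cat("  ...\n")
})

setMethod("show", "CommunityModel", function(object) {
  cat("CommunityModel:", length(object@taxa), "taxa,",
      nrow(object@S), "metabolite rows x", ncol(object@S), "reaction columns\n",
      " lumen metabolites:", length(object@dietColumns), "\n",
      " taxa:", paste(sprintf("%s(%.3f)", object@taxa, object@abundances),
                      collapse = ", "), "\n")
})

setMethod("show", "DietFluxes", function(object) {
  cat("DietFluxes:", length(object@fluxes), "compounds, units",
      object@unitState, "\n")
  tab <- table(object@provenance)
  cat(" provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "TradeoffSolution", function(object) {
  cat("TradeoffSolution [", object@status, "] alpha=", object@alpha,
      " muC=", format(object@muC, digits = 6),
      " muCmax=", format(object@muCMax, digits = 6), "\n", sep = "")
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:", object@combinationId,
      sprintf("SCFA=%.4g BCFA=%.4g alpha=%.2f [%s]\n",
              object@totalSCFA, object@totalBCFA, object@alphaUsed,
              object@solverStatus))
})
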