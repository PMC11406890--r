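# single-taxon FBA helper: growth rate of one reconstruction alone on a
# medium (assembled as a one-taxon community with abundance 1)
.singleTaxonGrowth <- function(model, medium, config = solverConfig()) {
  cm <- assembleCommunity(list(model),
                          abundanceProfile(stats::setNames(1, taxonId(model))))
  sol <- maximizeCommunityGrowth(cm, medium, config)
  if (sol@status == "infeasible") 0 else sol@muCMax
}

#' Complete a diet medium to a floor growth rate
#'
#' Food databases rarely list the trace nutrients (vitamins, cofactors,
#' minerals) that reconstructions require for biomass synthesis, so a diet
#' built purely from food tables can starve taxa outright.  For each taxon
#' this routine solves a linear programme minimising the total supplemental
#' flux needed for that taxon \emph{alone} to reach a growth rate of at
#' least \code{minGrowth} on diet + supplements; the completed medium adds
#' the element-wise maximum of the per-taxon supplement vectors on top of
#' the diet (provenance \code{"completion-supplement"}).  The
#' post-condition -- every taxon grows at \code{minGrowth} or more on the
#' completed medium -- is re-verified by single-taxon FBA before returning.
#'
#' Candidate supplements are the taxon's shared-lumen metabolites; a taxon
#' that cannot reach \code{minGrowth} even with every candidate
#' unconstrained raises a completion-impossible error naming it.
#'
#' @param taxa list of \linkS4class{TaxonModel}.
#' @param diet a per-hour \linkS4class{DietFluxes}.
#' @param minGrowth floor growth rate in 1/h (default 0.01).
#' @param config a [solverConfig()].
#' @return the completed \linkS4class{DietFluxes}, a superset of the
#'   input fluxes.
#' @export
completeMedium <- function(taxa, diet, minGrowth = 0.01,
                           config = solverConfig()) {
  stopifnot(methods::is(diet, "DietFluxes"))
  if (diet@unitState != "per-hour")
    stop("convert the diet to per-hour fluxes before completion")
  supplements <- numeric(0)
  for (model in taxa) {
    s <- .minimalSupplement(model, diet, minGrowth, config)
    for (cpd in names(s))
      supplements[cpd] <- max(if (cpd %in% names(supplements))
                                supplements[[cpd]] else 0, s[[cpd]])
  }
  supplements <- supplements[supplements > config$feasibilityTol]
  fl <- diet@fluxes; pv <- diet@provenance
  for (cpd in names(supplements)) {
    fl[cpd] <- (if (cpd %in% names(fl)) fl[[cpd]] else 0) + supplements[[cpd]]
    pv[cpd] <- "completion-supplement"
  }
  out <- methods::new("DietFluxes", fluxes = fl, provenance = pv[names(fl)],
                      unitState = "per-hour")
  for (model in taxa) {
    g <- .singleTaxonGrowth(model, out, config)
    if (g < minGrowth - 1e-6)
      stop("completion post-condition violated for taxon '", taxonId(model),
           "' (growth ", format(g), " < ", minGrowth, ")")
  }
  out
}

# LP: minimise sum of supplement fluxes subject to the taxon alone growing
# at >= minGrowth on diet + supplements
.minimalSupplement <- function(model, diet, minGrowth, config) {
  cm <- assembleCommunity(list(model),
                          abundanceProfile(stats::setNames(1, taxonId(model))))
  bnd <- .communityBounds(cm, diet)
  S <- as.matrix(cm@S)
  n <- ncol(S); m <- nrow(S)
  lumen <- names(cm@dietColumns)
  nsup <- length(lumen)
  # supplement columns: +1 supply into the lumen row, bounded [0, 1000]
  Asup <- matrix(0, m, nsup)
  lumen_rows <- match(lumen, rownames(S))
  for (k in seq_len(nsup)) Asup[lumen_rows[k], k] <- 1
  A <- cbind(S, Asup)
  lb <- c(bnd$lb, rep(0, nsup))
  ub <- c(bnd$ub, rep(1000, nsup))
  bm <- cm@biomassColumns[[1]]
  # feasibility probe: maximal growth with supplements wide open
  q0 <- numeric(n + nsup); q0[bm] <- -1
  probe <- .solveBoxQP(q0, numeric(n + nsup), A, numeric(m), lb, ub)
  if (probe$status == "infeasible" || -probe$obj < minGrowth - 1e-9)
    stop("completion-impossible error: taxon '", taxonId(model),
         "' cannot reach growth ", minGrowth, " even with unlimited supplements")
  # minimal supplement total with the growth floor imposed as a bound
  lb[bm] <- minGrowth
  q <- numeric(n + nsup); q[n + seq_len(nsup)] <- 1
  res <- .solveBoxQP(q, numeric(n + nsup), A, numeric(m), lb, ub)
  if (res$status == "infeasible")
    stop("completion-impossible error: taxon '", taxonId(model),
         "' has no feasible supplement at growth floor ", minGrowth)
  s <- res$x[n + seq_len(nsup)]
  names(s) <- lumen
  # small safety factor so the interior-point gap cannot leave the floor
  # growth rate infeasible by rounding
  s <- s * (1 + 1e-4)
  s[s > config$feasibilityTol]
}
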