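#' Organic-acid metabolite panels
#'
#' The short-chain fatty acid panel (acetate, propionate, butyrate) and
#' the branched-chain fatty acid panel (isobutyrate, isovalerate), the
#' screening readouts.  The two sets must be disjoint and non-empty.
#'
#' @param scfa,bcfa character vectors of compound ids.
#' @return a \code{MetabolitePanel} list.
#' @export
metabolitePanel <- function(scfa = c("acetate", "propionate", "butyrate"),
                            bcfa = c("isobutyrate", "isovalerate")) {
  stopifnot(length(scfa) > 0, length(bcfa) > 0,
            !length(intersect(scfa, bcfa)))
  structure(list(scfa = scfa, bcfa = bcfa), class = "MetabolitePanel")
}

#' Aggregate per-taxon secretion of a compound to the community total
#'
#' Community production of a metabolite is the abundance-weighted sum of
#' the per-taxon exchange fluxes for that compound, in mmol/(gDW h) of
#' total community biomass.  By default only net producers contribute
#' (negative exchanges, i.e. consumers, are clipped at zero) so that
#' cross-feeding cannot mask production; \code{mode = "net"} gives the
#' plain weighted sum.
#'
#' @param model the \linkS4class{CommunityModel}.
#' @param sol a \linkS4class{TradeoffSolution} for that model.
#' @param compound lumen compound id.
#' @param mode \code{"producers"} (default) or \code{"net"}.
#' @return the aggregated flux (numeric scalar).
#' @export
aggregateMetaboliteFlux <- function(model, sol, compound,
                                    mode = c("producers", "net")) {
  mode <- match.arg(mode)
  info <- model@reactionInfo
  sel <- which(info$type == "exchange" & info$metabolite == compound)
  if (!length(sel)) {
    if (!compound %in% names(model@dietColumns))
      stop("missing-compound error: no exchange for '", compound, "'")
    return(0)
  }
  v <- as.numeric(sol@fluxes[sel])
  a <- model@abundances[info$taxon[sel]]
  if (mode == "producers") v <- pmax(v, 0)
  sum(a * v)
}

#' Panel totals
#'
#' Sums a compound -> flux mapping over the SCFA and BCFA panels;
#' compounds absent from the mapping count as zero and compounds outside
#' the panels are ignored.
#'
#' @param fluxes named numeric of aggregated compound fluxes.
#' @param panel a [metabolitePanel()].
#' @return named numeric \code{c(total_scfa, total_bcfa)}.
#' @export
panelTotals <- function(fluxes, panel = metabolitePanel()) {
  tot <- function(set) sum(fluxes[intersect(set, names(fluxes))], na.rm = TRUE)
  c(total_scfa = tot(panel$scfa), total_bcfa = tot(panel$bcfa))
}

#' Relative variation versus the control
#'
#' Signed percent change, \code{100 * (combo - control) / control}.
#' Undefined when the control flux is zero: returns \code{NA} (rendered
#' as such in reports, never as a number).
#'
#' @param comboValue flux under the food-containing diet.
#' @param controlValue flux under the milk-only control.
#' @return percent change, or \code{NA_real_} when undefined.
#' @export
relativeVariation <- function(comboValue, controlValue) {
  if (!is.finite(controlValue) || controlValue == 0) return(NA_real_)
  100 * (comboValue - controlValue) / controlValue
}

#' Classify a relative variation
#'
#' \code{increase} above the no-change band, \code{decrease} below it,
#' \code{no-change} inside \code{[-band, +band]} percent (default 1).
#'
#' @param rel relative variation in percent (must be a defined number).
#' @param noChangeBand half-width of the no-change band in percent.
#' @return \code{"increase"}, \code{"decrease"} or \code{"no-change"}.
#' @export
classifyCombination <- function(rel, noChangeBand = 1.0) {
  if (!is.finite(rel)) stop("relative variation is undefined; cannot classify")
  if (rel > noChangeBand) "increase"
  else if (rel < -noChangeBand) "decrease"
  else "no-change"
}

#' Screen configuration
#'
#' Caloric layout, absorption handling, host secretions, completion floor
#' and classification band for [runScreen()].
#'
#' @param totalEnergy kcal/day (default 608, a 6-month-old's requirement).
#' @param milkFraction caloric fraction of breastmilk in every
#'   combination (default 0.85).
#' @param milkId food id of the breastmilk item.
#' @param formulaId optional food id of an infant-formula item, run as a
#'   second control at fraction 1.
#' @param absorptionFactor fraction of absorbable compounds reaching the
#'   colon (default 0.2).
#' @param absorbed absorbed-compound set; \code{NULL} derives it from the
#'   food table's absorbable flags.
#' @param secretions host secretions in mmol/h.
#' @param minGrowth completion floor growth rate (1/h).
#' @param noChangeBand classification band half-width in percent.
#' @param aggregate \code{"producers"} or \code{"net"} (see
#'   [aggregateMetaboliteFlux()]).
#' @param panel a [metabolitePanel()].
#' @param solver a [solverConfig()].
#' @param renormalize renormalise the abundance profile after filtering
#'   (default TRUE).
#' @return a \code{ScreenConfig} list.
#' @export
screenConfig <- function(totalEnergy = 608,
                         milkFraction = 0.85,
                         milkId = "breastmilk",
                         formulaId = NULL,
                         absorptionFactor = 0.2,
                         absorbed = NULL,
                         secretions = defaultHostSecretions(),
                         minGrowth = 0.01,
                         noChangeBand = 1.0,
                         aggregate = c("producers", "net"),
                         panel = metabolitePanel(),
                         solver = solverConfig(),
                         renormalize = TRUE) {
  aggregate <- match.arg(aggregate)
  stopifnot(milkFraction > 0, milkFraction < 1, totalEnergy > 0,
            noChangeBand >= 0)
  structure(list(totalEnergy = totalEnergy, milkFraction = milkFraction,
                 milkId = milkId, formulaId = formulaId,
                 absorptionFactor = absorptionFactor, absorbed = absorbed,
                 secretions = secretions, minGrowth = minGrowth,
                 noChangeBand = noChangeBand, aggregate = aggregate,
                 panel = panel, solver = solver, renormalize = renormalize),
            class = "ScreenConfig")
}

#' Read a screen configuration from YAML
#'
#' Recognised keys mirror the [screenConfig()] arguments (plus nested
#' \code{solver} keys passed to [solverConfig()]).
#'
#' @param path YAML file.
#' @return a \code{ScreenConfig}.
#' @export
readScreenConfig <- function(path) {
  y <- yaml::read_yaml(path)
  solver <- if (!is.null(y$solver)) do.call(solverConfig, y$solver)
            else solverConfig()
  y$solver <- NULL
  if (!is.null(y$secretions)) y$secretions <- unlist(y$secretions)
  if (!is.null(y$absorbed)) y$absorbed <- unlist(y$absorbed)
  if (!is.null(y$panel)) y$panel <- do.call(metabolitePanel, lapply(y$panel, unlist))
  do.call(screenConfig, c(y, list(solver = solver)))
}

#' All unordered pairs of complementary foods
#'
#' @param foods named list of \linkS4class{FoodItem}.
#' @param exclude food ids to leave out (controls).
#' @return two-column character matrix of food-id pairs.
#' @export
allFoodPairs <- function(foods, exclude = character()) {
  ids <- setdiff(names(foods), exclude)
  if (length(ids) < 2) return(matrix(character(), ncol = 2))
  t(utils::combn(ids, 2))
}

# process one diet design through the full medium pipeline
.designToMedium <- function(design, foods, models, config) {
  absorbed <- if (is.null(config$absorbed)) absorbedCompounds(foods)
              else config$absorbed
  diet <- buildDiet(design, foods)
  diet <- convertToHourly(diet)
  diet <- applyAbsorption(diet, absorbed, config$absorptionFactor)
  diet <- addHostSecretions(diet, config$secretions, absorbed = absorbed)
  completeMedium(models, diet, config$minGrowth, config$solver)
}

.combinationDesigns <- function(foods, pairs, config) {
  milk <- config$milkId
  if (!milk %in% names(foods))
    stop("food table lacks the milk control item '", milk, "'")
  exclude <- c(milk, config$formulaId)
  singles <- setdiff(names(foods), exclude)
  designs <- list()
  designs[[milk]] <- dietDesign(stats::setNames(1, milk), config$totalEnergy)
  if (!is.null(config$formulaId) && config$formulaId %in% names(foods))
    designs[[config$formulaId]] <-
      dietDesign(stats::setNames(1, config$formulaId), config$totalEnergy)
  for (f in singles) {
    comp <- stats::setNames(c(1 - config$milkFraction, config$milkFraction),
                            c(f, milk))
    designs[[paste(f, milk, sep = "+")]] <- dietDesign(comp, config$totalEnergy)
  }
  if (!is.null(pairs) && nrow(pairs)) {
    half <- (1 - config$milkFraction) / 2
    for (i in seq_len(nrow(pairs))) {
      f1 <- pairs[i, 1]; f2 <- pairs[i, 2]
      comp <- stats::setNames(c(half, half, config$milkFraction),
                              c(f1, f2, milk))
      designs[[paste(f1, f2, milk, sep = "+")]] <-
        dietDesign(comp, config$totalEnergy)
    }
  }
  designs
}

#' Screen food-breastmilk combinations
#'
#' Runs the full pipeline for every combination: diet construction, unit
#' conversion, absorption adjustment, host secretions, medium completion,
#' optimal-trade-off community FBA, metabolite aggregation, panel totals,
#' relative variation versus the milk-only control and classification.
#' The milk-only control is always included (and, when \code{formulaId}
#' is set, an infant-formula control at caloric fraction 1).  Solver
#' failures are recorded in the affected \linkS4class{ScreenResult} and
#' the screen continues.
#'
#' Results are sorted by predicted total SCFA flux, descending; a summary
#' of increase/decrease/no-change counts per panel is emitted via
#' \code{message()}.
#'
#' @param foods named list of \linkS4class{FoodItem} (must contain the
#'   milk item).
#' @param community an assembled \linkS4class{CommunityModel}.
#' @param pairs optional two-column matrix of food-id pairs (see
#'   [allFoodPairs()]); \code{NULL} screens single foods only.
#' @param config a [screenConfig()].
#' @return list of \linkS4class{ScreenResult}, sorted.
#' @export
runScreen <- function(foods, community, pairs = NULL,
                      config = screenConfig()) {
  stopifnot(methods::is(community, "CommunityModel"))
  models <- community@models
  designs <- .combinationDesigns(foods, pairs, config)
  compounds <- names(community@dietColumns)
  evalOne <- function(id, design) {
    medium <- .designToMedium(design, foods, models, config)
    sol <- findOptimalAlpha(community, medium, config$solver)
    if (sol@status == "infeasible")
      return(list(fluxes = stats::setNames(rep(NA_real_, length(compounds)),
                                           compounds),
                  mu = stats::setNames(rep(NA_real_, length(community@taxa)),
                                       community@taxa),
                  alpha = NA_real_, status = "infeasible"))
    fl <- vapply(compounds, function(cpd)
      aggregateMetaboliteFlux(community, sol, cpd, config$aggregate),
      numeric(1))
    list(fluxes = fl, mu = growthRates(sol), alpha = sol@alpha,
         status = sol@status)
  }
  raw <- vector("list", length(designs))
  names(raw) <- names(designs)
  for (id in names(designs)) {
    raw[[id]] <- tryCatch(evalOne(id, designs[[id]]), error = function(e) {
      warning("combination '", id, "' failed: ", conditionMessage(e))
      list(fluxes = stats::setNames(rep(NA_real_, length(compounds)), compounds),
           mu = stats::setNames(rep(NA_real_, length(community@taxa)),
                                community@taxa),
           alpha = NA_real_, status = "error")
    })
  }
  ctrl <- raw[[config$milkId]]
  ctrl_tot <- panelTotals(ctrl$fluxes, config$panel)
  results <- lapply(names(raw), function(id) {
    r <- raw[[id]]
    tot <- panelTotals(r$fluxes, config$panel)
    rel_m <- vapply(compounds, function(cpd)
      relativeVariation(r$fluxes[[cpd]], ctrl$fluxes[[cpd]]), numeric(1))
    rel_p <- c(total_scfa = relativeVariation(tot[["total_scfa"]],
                                              ctrl_tot[["total_scfa"]]),
               total_bcfa = relativeVariation(tot[["total_bcfa"]],
                                              ctrl_tot[["total_bcfa"]]))
    rel_g <- vapply(community@taxa, function(tx)
      relativeVariation(r$mu[[tx]], ctrl$mu[[tx]]), numeric(1))
    cls <- vapply(rel_p, function(x)
      if (is.finite(x)) classifyCombination(x, config$noChangeBand)
      else NA_character_, character(1))
    methods::new("ScreenResult",
                 combinationId = id,
                 metaboliteFluxes = r$fluxes,
                 totalSCFA = tot[["total_scfa"]],
                 totalBCFA = tot[["total_bcfa"]],
                 relVariation = c(rel_m, rel_p),
                 growthRelVariation = rel_g,
                 classification = cls,
                 alphaUsed = r$alpha,
                 solverStatus = r$status)
  })
  ord <- order(-vapply(results, function(r) r@totalSCFA, numeric(1)))
  results <- results[ord]
  for (p in c("total_scfa", "total_bcfa")) {
    cl <- vapply(results, function(r) r@classification[[p]], character(1))
    message(sprintf("screen summary [%s]: %d increase, %d decrease, %d no-change",
                    p, sum(cl == "increase", na.rm = TRUE),
                    sum(cl == "decrease", na.rm = TRUE),
                    sum(cl == "no-change", na.rm = TRUE)))
  }
  results
}

#' Export a screen report
#'
#' Writes a relative-variation matrix (combinations x metabolites and
#' panels, TSV; undefined cells rendered as \code{NA}) plus a JSON dump
#' that reloads losslessly via [readScreenResults()].
#'
#' @param results list of \linkS4class{ScreenResult} from [runScreen()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
exportReport <- function(results, dir) {
  if (!length(results)) stop("nonempty results required")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- names(results[[1]]@relVariation)
  mat <- do.call(rbind, lapply(results, function(r)
    r@relVariation[cols]))
  tab <- data.frame(combination = vapply(results, function(r)
    r@combinationId, character(1)), mat, check.names = FALSE)
  tsv <- file.path(dir, "screen_relative_variation.tsv")
  utils::write.table(format(tab, digits = 10, trim = TRUE, nsmall = 0),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  json <- file.path(dir, "screen_results.json")
  jsonlite::write_json(lapply(results, function(r) list(
    combination_id = r@combinationId,
    metabolite_fluxes = as.list(r@metaboliteFluxes),
    total_scfa = r@totalSCFA,
    total_bcfa = r@totalBCFA,
    rel_variation = as.list(r@relVariation),
    growth_rel_variation = as.list(r@growthRelVariation),
    classification = as.list(r@classification),
    alpha_used = r@alphaUsed,
    solver_status = r@solverStatus)),
    json, auto_unbox = TRUE, digits = I(17), pretty = TRUE, na = "null")
  c(tsv = tsv, json = json)
}

#' @rdname exportReport
#' @param path JSON file written by [exportReport()].
#' @export
readScreenResults <- function(path) {
  docs <- jsonlite::read_json(path)
  lapply(docs, function(d) {
    num <- function(x) vapply(x, function(v)
      if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
    chr <- function(x) vapply(x, function(v)
      if (is.null(v)) NA_character_ else as.character(v), character(1))
    methods::new("ScreenResult",
                 combinationId = d$combination_id,
                 metaboliteFluxes = num(d$metabolite_fluxes),
                 totalSCFA = as.numeric(d$total_scfa),
                 totalBCFA = as.numeric(d$total_bcfa),
                 relVariation = num(d$rel_variation),
                 growthRelVariation = num(d$growth_rel_variation),
                 classification = chr(d$classification),
                 alphaUsed = if (is.null(d$alpha_used)) NA_real_
                             else as.numeric(d$alpha_used),
                 solverStatus = d$solver_status)
  })
}
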