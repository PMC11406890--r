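#' Solver configuration
#'
#' Tolerances and the trade-off grid used by the community solvers.
#'
#' @param feasibilityTol absolute tolerance on |S v| (default 1e-8).
#' @param optimalityTol relative optimality tolerance (default 1e-8).
#' @param negligibleGrowth growth rates at or below this value (1/h) count
#'   as "not growing" (default 1e-6).
#' @param alphaGrid strictly descending trade-off grid in (0, 1]; default
#'   1.0, 0.9, ..., 0.1.
#' @param tradeoffNorm \code{"l2"} (default; minimise the squared growth
#'   rates, whose unconstrained optimum is alpha * muCmax * a / (a'a)) or
#'   \code{"l1"} for a sensitivity variant.
#' @param fluxPolish logical; resolve residual flux degeneracy by a
#'   secondary minimal-total-flux step with growth rates held fixed
#'   (default TRUE).
#' @return a validated \code{SolverConfig} list.
#' @export
solverConfig <- function(feasibilityTol = 1e-8,
                         optimalityTol = 1e-8,
                         negligibleGrowth = 1e-6,
                         alphaGrid = seq(1.0, 0.1, by = -0.1),
                         tradeoffNorm = c("l2", "l1"),
                         fluxPolish = TRUE) {
  tradeoffNorm <- match.arg(tradeoffNorm)
  stopifnot(feasibilityTol > 0, optimalityTol > 0, negligibleGrowth > 0,
            length(alphaGrid) >= 1, all(alphaGrid > 0), all(alphaGrid <= 1),
            all(diff(alphaGrid) < 0))
  structure(list(feasibilityTol = feasibilityTol,
                 optimalityTol = optimalityTol,
                 negligibleGrowth = negligibleGrowth,
                 alphaGrid = alphaGrid,
                 tradeoffNorm = tradeoffNorm,
                 fluxPolish = fluxPolish),
            class = "SolverConfig")
}

# medium -> column bounds; compounds absent from the model are logged and
# ignored, lumen metabolites absent from the medium stay closed (lb 0)
.communityBounds <- function(model, medium) {
  stopifnot(methods::is(model, "CommunityModel"))
  lb <- model@lb; ub <- model@ub
  if (!is.null(medium)) {
    stopifnot(methods::is(medium, "DietFluxes"))
    if (medium@unitState != "per-hour")
      stop("medium must be converted to per-hour fluxes before solving")
    fl <- medium@fluxes
    known <- names(fl) %in% names(model@dietColumns)
    if (any(!known))
      message("medium compound(s) without lumen metabolite, ignored: ",
              paste(names(fl)[!known], collapse = ", "))
    for (cm in names(fl)[known])
      lb[model@dietColumns[[cm]]] <- -fl[[cm]]
  }
  list(lb = lb, ub = ub)
}

.asSolution <- function(model, x, status, alpha, muCMax,
                        trace = data.frame()) {
  a <- model@abundances
  mu <- stats::setNames(pmax(x[model@biomassColumns], 0), model@taxa)
  attr(mu, "abundances") <- a
  methods::new("TradeoffSolution",
               muC = sum(a * mu),
               muCMax = muCMax,
               mu = mu,
               alpha = alpha,
               fluxes = stats::setNames(x, colnames(model@S)),
               status = status,
               trace = trace)
}

#' Maximise community growth (plain community FBA)
#'
#' Solves the linear programme max sum_i a_i mu_i subject to S v = 0 and
#' the flux bounds implied by the medium, the first step of the
#' cooperative trade-off.  No allocation step is performed; the recorded
#' alpha is 1.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param medium a per-hour \linkS4class{DietFluxes} (or \code{NULL} for a
#'   closed medium).
#' @param config a [solverConfig()].
#' @return a \linkS4class{TradeoffSolution}.
#' @export
maximizeCommunityGrowth <- function(model, medium = NULL,
                                    config = solverConfig()) {
  bnd <- .communityBounds(model, medium)
  n <- ncol(model@S)
  q <- numeric(n)
  q[model@biomassColumns] <- -model@abundances
  res <- .solveBoxQP(q, numeric(n), as.matrix(model@S), numeric(nrow(model@S)),
                     bnd$lb, bnd$ub, tol = config$optimalityTol * 10)
  if (res$status == "infeasible")
    return(methods::new("TradeoffSolution", muC = NA_real_, muCMax = NA_real_,
                        mu = stats::setNames(rep(NA_real_, length(model@taxa)),
                                             model@taxa),
                        alpha = 1, fluxes = numeric(), status = "infeasible",
                        trace = data.frame()))
  muCMax <- -res$obj
  .asSolution(model, res$x, res$status, alpha = 1, muCMax = muCMax)
}

# step 2 of the trade-off for one alpha given muCmax; returns a solution
.tradeoffAllocate <- function(model, bnd, alpha, muCMax, config) {
  S <- as.matrix(model@S)
  n <- ncol(S); m <- nrow(S)
  a <- model@abundances
  bmcol <- model@biomassColumns
  # extra row: sum_i a_i mu_i - slack = alpha * muCmax, slack >= 0
  A <- rbind(cbind(S, 0), 0)
  A[m + 1, bmcol] <- a
  A[m + 1, n + 1] <- -1
  b <- c(numeric(m), alpha * muCMax)
  slack_ub <- max(1, muCMax)
  lb <- c(bnd$lb, 0); ub <- c(bnd$ub, slack_ub)
  q <- numeric(n + 1); h <- numeric(n + 1)
  if (config$tradeoffNorm == "l2") h[bmcol] <- 2 else q[bmcol] <- 1
  res <- .solveBoxQP(q, h, A, b, lb, ub, tol = config$optimalityTol * 10)
  x <- res$x[seq_len(n)]
  status <- res$status
  if (status == "optimal" && config$fluxPolish) {
    px <- .polishFluxes(S, bnd, x, bmcol)
    if (!is.null(px)) x <- px
  }
  .asSolution(model, x, status, alpha = alpha, muCMax = muCMax)
}

# minimal-total-flux polish: minimise sum |v_j| over non-biomass columns
# with growth rates pinned at the allocation optimum (v = p - n split)
.polishFluxes <- function(S, bnd, x, bmcol) {
  n <- ncol(S)
  lb <- bnd$lb; ub <- bnd$ub
  lb[bmcol] <- x[bmcol]; ub[bmcol] <- x[bmcol]
  A <- cbind(S, -S)
  pl <- pmax(lb, 0); pu <- pmax(ub, 0)
  nl <- pmax(-ub, 0); nu <- pmax(-lb, 0)
  q <- rep(1, 2 * n)
  q[c(bmcol, n + bmcol)] <- 0
  res <- .solveBoxQP(q, numeric(2 * n), A, numeric(nrow(S)),
                     c(pl, nl), c(pu, nu))
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)] - res$x[n + seq_len(n)]
}

#' Cooperative trade-off growth allocation
#'
#' Two-step scheme: step 1 maximises community growth to obtain muCmax;
#' step 2 minimises the squared per-taxon growth rates subject to all FBA
#' constraints plus sum_i a_i mu_i >= alpha * muCmax.  When no other
#' constraint binds, the allocation has the closed form
#' mu_i = alpha * muCmax * a_i / (a' a), i.e. growth proportional to
#' relative abundance.  A step-2 solve that fails to reach optimality is
#' returned with status \code{numerically-unstable} (partial solution
#' retained).
#'
#' @inheritParams maximizeCommunityGrowth
#' @param alpha trade-off fraction in (0, 1].
#' @return a \linkS4class{TradeoffSolution}.
#' @export
cooperativeTradeoff <- function(model, medium = NULL, alpha,
                                config = solverConfig()) {
  stopifnot(alpha > 0, alpha <= 1)
  step1 <- maximizeCommunityGrowth(model, medium, config)
  if (step1@status == "infeasible") return(step1)
  bnd <- .communityBounds(model, medium)
  sol <- .tradeoffAllocate(model, bnd, alpha, step1@muCMax, config)
  sol
}

#' Optimal trade-off search
#'
#' Evaluates the cooperative trade-off over a descending alpha grid and
#' returns the solution at the largest alpha for which the number of taxa
#' growing above the negligible-growth threshold is maximal (the scan
#' stops early once every taxon grows, since the count cannot improve).
#' The full scan trace (alpha, community growth, growing-taxon count,
#' status) is attached to the returned solution.
#'
#' @inheritParams maximizeCommunityGrowth
#' @return a \linkS4class{TradeoffSolution} with the scan trace in
#'   \code{@trace}.
#' @export
findOptimalAlpha <- function(model, medium = NULL, config = solverConfig()) {
  grid <- config$alphaGrid
  step1 <- maximizeCommunityGrowth(model, medium, config)
  if (step1@status == "infeasible") {
    step1@trace <- data.frame(alpha = grid, muC = NA_real_, nGrowing = NA_integer_,
                              status = "infeasible")
    return(step1)
  }
  bnd <- .communityBounds(model, medium)
  ntax <- length(model@taxa)
  sols <- vector("list", length(grid))
  trace <- data.frame(alpha = numeric(), muC = numeric(),
                      nGrowing = integer(), status = character())
  best <- 0L; best_idx <- NA_integer_
  for (g in seq_along(grid)) {
    sol <- .tradeoffAllocate(model, bnd, grid[g], step1@muCMax, config)
    ngrow <- sum(sol@mu > config$negligibleGrowth)
    trace <- rbind(trace, data.frame(alpha = grid[g], muC = sol@muC,
                                     nGrowing = ngrow, status = sol@status))
    sols[[g]] <- sol
    if (sol@status != "infeasible" && ngrow > best) {
      best <- ngrow; best_idx <- g
    }
    if (best == ntax) break                      # early exit: cannot improve
  }
  if (is.na(best_idx)) {
    out <- sols[[1]]
  } else {
    out <- sols[[best_idx]]
  }
  out@trace <- trace
  out
}

#' Validate a trade-off solution against its model
#'
#' Pure check: recomputes the steady-state residual max |S v|, the
#' community-growth identity |mu_c - sum_i a_i mu_i|, counts taxa at or
#' below the negligible-growth threshold, and reports whether the
#' trade-off was respected (every taxon above the threshold) -- the
#' diagnostic used to flag numerically unstable allocations.
#'
#' @param model the \linkS4class{CommunityModel} the solution came from.
#' @param sol a \linkS4class{TradeoffSolution} with status optimal or
#'   numerically-unstable.
#' @param config a [solverConfig()].
#' @return a list with elements \code{maxResidual}, \code{muCResidual},
#'   \code{nNegligible}, \code{tradeoffRespected}.
#' @export
checkSolution <- function(model, sol, config = solverConfig()) {
  stopifnot(sol@status %in% c("optimal", "numerically-unstable"))
  v <- sol@fluxes
  resid <- max(abs(as.numeric(model@S %*% v)))
  mu_res <- abs(sol@muC - sum(model@abundances * sol@mu))
  n_neg <- sum(sol@mu <= config$negligibleGrowth)
  list(maxResidual = resid,
       muCResidual = mu_res,
       nNegligible = n_neg,
       tradeoffRespected = n_neg == 0L)
}

#' Serialise a solution
#'
#' \code{writeSolutionJSON} writes growth rates, alpha, status and
#' residuals to JSON; \code{writeFluxesTSV} writes the full flux vector as
#' a three-column TSV (reaction, taxon, flux).
#'
#' @param sol a \linkS4class{TradeoffSolution}.
#' @param model the originating \linkS4class{CommunityModel} (for
#'   residuals / column metadata).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSolutionJSON <- function(sol, model, path) {
  chk <- checkSolution(model, sol)
  doc <- list(status = sol@status,
              alpha = sol@alpha,
              mu_c = sol@muC,
              mu_c_max = sol@muCMax,
              mu = as.list(growthRates(sol)),
              residuals = list(steady_state = chk$maxResidual,
                               mu_identity = chk$muCResidual))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSolutionJSON
#' @export
writeFluxesTSV <- function(sol, model, path) {
  info <- model@reactionInfo
  out <- data.frame(reaction = info$id,
                    taxon = ifelse(is.na(info$taxon), "medium", info$taxon),
                    flux = as.numeric(sol@fluxes),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
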