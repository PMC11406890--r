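# Independent oracles and toy-model builders shared across the suite.
# The oracles never call the package's interior-point solver.

# Brute-force LP oracle: maximise q'x subject to A x = b, l <= x <= u by
# enumerating basic solutions (vertices).  Only for tiny problems.
vertexEnumLP <- function(q, A, b = numeric(nrow(A)), l, u) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  if (r < nrow(A)) {                       # drop dependent rows
    rows <- qr(t(A))$pivot[seq_len(r)]
    A <- A[rows, , drop = FALSE]
    b <- b[rows]
  }
  best <- -Inf
  bestx <- NULL
  basics <- if (r == 0) list(integer()) else utils::combn(n, r, simplify = FALSE)
  for (B in basics) {
    AB <- A[, B, drop = FALSE]
    if (length(B) && abs(det(AB)) < 1e-10) next
    N <- setdiff(seq_len(n), B)
    for (mask in 0:(2^length(N) - 1)) {
      xN <- ifelse(bitwAnd(mask, 2^(seq_along(N) - 1)) > 0, u[N], l[N])
      x <- numeric(n)
      x[N] <- xN
      if (length(B)) {
        rhs <- b - if (length(N)) drop(A[, N, drop = FALSE] %*% xN) else 0
        x[B] <- drop(solve(AB, rhs))
      }
      if (all(x >= l - 1e-9) && all(x <= u + 1e-9)) {
        v <- sum(q * x)
        if (v > best) {
          best <- v
          bestx <- x
        }
      }
    }
  }
  list(obj = best, x = bestx)
}

# community LP pieces for the oracle: objective + constraint data
communityLPData <- function(model, medium) {
  bnd <- weanflux:::.communityBounds(model, medium)
  q <- numeric(ncol(model@S))
  q[model@biomassColumns] <- model@abundances
  list(q = q, A = as.matrix(model@S), b = numeric(nrow(model@S)),
       l = bnd$lb, u = bnd$ub)
}

# one-substrate toy taxon: EX_S (uptake), CAT (S -> yield biomass + products),
# product exchanges (secretion only), biomass
makeToyTaxon <- function(taxonId, substrate = "S", yield = 0.5,
                         products = c()) {
  subs <- list()
  subs[[substrate]] <- list(yield = yield, products = products)
  genTaxon(archetypeSpec("generalist", subs), taxonId)
}

# random small community: 2 taxa with one product each, or 3 lean taxa
# (no products) so the vertex oracle stays cheap; exclusive or shared
# substrates
randomToyCommunity <- function(seed) {
  set.seed(seed)
  ntax <- sample(2:3, 1)
  shared <- stats::runif(1) < 0.4
  lean <- ntax == 3
  taxa <- paste0("T", seq_len(ntax))
  models <- lapply(seq_len(ntax), function(i) {
    sub <- if (shared) "S" else paste0("S", i)
    makeToyTaxon(taxa[i], sub, yield = stats::runif(1, 0.2, 0.8),
                 products = if (lean) c() else c(P = stats::runif(1, 0.5, 2)))
  })
  a <- stats::runif(ntax, 0.2, 1)
  a <- a / sum(a)
  profile <- abundanceProfile(stats::setNames(a, taxa))
  subs <- unique(unlist(lapply(models, function(m) {
    met <- metabolites(m)
    grep("^S", met$id[met$compartment == "shared-lumen"], value = TRUE)
  })))
  medium <- methods::new("DietFluxes",
    fluxes = stats::setNames(stats::runif(length(subs), 1, 20), subs),
    provenance = stats::setNames(rep("food", length(subs)), subs),
    unitState = "per-hour")
  cm <- assembleCommunity(models, profile)
  list(model = cm, medium = medium, profile = profile, models = models)
}

# shared-substrate equal-yield community: only the community-growth
# constraint binds in the trade-off, so the closed form applies exactly
sharedSubstrateCommunity <- function(seed, ntax = 2, yield = 1, supply = 10) {
  set.seed(seed)
  taxa <- paste0("T", seq_len(ntax))
  models <- lapply(taxa, function(tx) makeToyTaxon(tx, "S", yield = yield))
  a <- stats::runif(ntax, 0.2, 1)
  a <- a / sum(a)
  profile <- abundanceProfile(stats::setNames(a, taxa))
  medium <- methods::new("DietFluxes",
    fluxes = c(S = supply), provenance = c(S = "food"),
    unitState = "per-hour")
  list(model = assembleCommunity(models, profile), medium = medium,
       abundances = stats::setNames(a, taxa), yield = yield, supply = supply)
}

# tiny strict-convex QP oracle by active-set enumeration:
#   minimise sum(mu^2) s.t. a'mu >= c0, 0 <= mu <= cap  (elementwise)
# exact KKT solution for each active set, feasibility-checked
muAllocOracle <- function(a, c0, cap) {
  n <- length(a)
  best <- NULL
  bestval <- Inf
  for (maskU in 0:(2^n - 1)) {      # variables pinned at their caps
    atcap <- bitwAnd(maskU, 2^(seq_len(n) - 1)) > 0
    for (tight in c(TRUE, FALSE)) { # growth constraint active or not
      mu <- numeric(n)
      mu[atcap] <- cap[atcap]
      free <- !atcap
      if (tight) {
        resid <- c0 - sum(a[atcap] * mu[atcap])
        if (any(free)) {
          lam <- 2 * resid / sum(a[free]^2)
          if (lam < -1e-9) next      # multiplier must be >= 0
          mu[free] <- lam * a[free] / 2
        } else if (resid > 1e-9) next
      } else {
        mu[free] <- 0
      }
      if (any(mu < -1e-9) || any(mu > cap + 1e-9)) next
      if (sum(a * mu) < c0 - 1e-9) next
      val <- sum(mu^2)
      if (val < bestval - 1e-12) {
        bestval <- val
        best <- mu
      }
    }
  }
  best
}
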