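#' Create an abundance profile
#'
#' @param abundances named numeric vector of relative abundances (> 0,
#'   summing to at most 1).
#' @param sourceLabel free-text provenance label.
#' @return an \linkS4class{AbundanceProfile}.
#' @export
abundanceProfile <- function(abundances, sourceLabel = "unspecified") {
  methods::new("AbundanceProfile", abundances = abundances,
               sourceLabel = sourceLabel)
}

#' Load a genus abundance table
#'
#' Reads a tab-separated table with header columns \code{taxon} and
#' \code{abundance} (UTF-8), as produced by collapsing amplicon data at
#' the genus level and averaging across samples.
#'
#' @param path TSV file path.
#' @return an \linkS4class{AbundanceProfile}.
#' @export
loadAbundances <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("taxon", "abundance") %in% names(tab)))
    stop("abundance table needs columns 'taxon' and 'abundance'")
  if (anyDuplicated(tab$taxon))
    stop("validation error: duplicate taxon ",
         paste(unique(tab$taxon[duplicated(tab$taxon)]), collapse = ", "))
  ab <- suppressWarnings(as.numeric(tab$abundance))
  if (anyNA(ab))
    stop("validation error: non-numeric abundance for ",
         paste(tab$taxon[is.na(ab)], collapse = ", "))
  if (any(ab <= 0))
    stop("validation error: non-positive abundance for ",
         paste(tab$taxon[ab <= 0], collapse = ", "))
  abundanceProfile(stats::setNames(ab, tab$taxon), sourceLabel = path)
}

#' Filter low-abundance taxa
#'
#' Retains exactly the taxa with relative abundance at or above
#' \code{threshold} (default 1\%).  Low-abundance taxa contribute little
#' to community metabolite totals but inflate model size and provoke
#' numerical instability, so they are dropped before assembly.  The result
#' is \emph{not} renormalised; see [renormalizeProfile()].
#'
#' Retained count and retained mass are stored in the profile's
#' \code{info} slot and reported via \code{message()}.
#'
#' @param profile an \linkS4class{AbundanceProfile}.
#' @param threshold abundance fraction in (0, 1); default 0.01.
#' @return the filtered \linkS4class{AbundanceProfile}.
#' @export
filterAbundances <- function(profile, threshold = 0.01) {
  stopifnot(methods::is(profile, "AbundanceProfile"),
            threshold > 0, threshold < 1)
  a <- profile@abundances
  keep <- a >= threshold
  if (!any(keep))
    stop("empty-community error: no taxon at or above threshold ", threshold)
  out <- abundanceProfile(a[keep], sourceLabel = profile@sourceLabel)
  out@info <- c(profile@info,
                list(retained = sum(keep), retainedMass = sum(a[keep]),
                     filterThreshold = threshold))
  message(sprintf("filterAbundances: retained %d/%d taxa, mass %.4f",
                  sum(keep), length(a), sum(a[keep])))
  out
}

#' Renormalise an abundance profile to sum to 1
#'
#' Divides every abundance by the current total, preserving abundance
#' ratios.  Applied after filtering so that the retained community is
#' treated as the whole community (a modelling choice, switchable in
#' [runScreen()] via \code{renormalize = FALSE}).
#'
#' @param profile an \linkS4class{AbundanceProfile}.
#' @return renormalised \linkS4class{AbundanceProfile} (sum 1 within 1e-9).
#' @export
renormalizeProfile <- function(profile) {
  stopifnot(methods::is(profile, "AbundanceProfile"))
  a <- profile@abundances
  if (!length(a) || sum(a) <= 0)
    stop("empty-community error: nothing to renormalize")
  out <- abundanceProfile(a / sum(a), sourceLabel = profile@sourceLabel)
  out@info <- profile@info
  out
}

#' Assemble the abundance-weighted community model
#'
#' Builds the block community stoichiometric matrix.  Every taxon keeps
#' its own rows for internal metabolites and its own columns for all
#' reactions; shared-lumen metabolites are merged into single community
#' rows in which each taxon's exchange flux enters multiplied by that
#' taxon's relative abundance a_i (taxon fluxes are per gDW of the taxon,
#' community balances per gDW of total community biomass).  One diet
#' exchange column per lumen metabolite is appended (coefficient -1 on the
#' lumen row, i.e. export from the lumen; uptake by the community is
#' negative diet-exchange flux and is bounded below by the medium at solve
#' time).  At steady state every lumen row therefore enforces
#' sum_i a_i v_i^ex,m = v^diet,m with v^diet,m >= -(diet flux of m).
#'
#' The community growth rate mu_c = sum_i a_i mu_i is represented through
#' the per-taxon biomass columns; no extra column is added for it.
#'
#' @param models list of \linkS4class{TaxonModel}, one per profile taxon
#'   (matched by taxon id).
#' @param profile normalised \linkS4class{AbundanceProfile}.
#' @return a \linkS4class{CommunityModel}.
#' @export
assembleCommunity <- function(models, profile) {
  stopifnot(methods::is(profile, "AbundanceProfile"))
  a <- profile@abundances
  if (abs(sum(a) - 1) > 1e-6)
    stop("profile must be renormalized before assembly (sum = ",
         format(sum(a)), ")")
  model_ids <- vapply(models, taxonId, character(1))
  miss <- setdiff(names(a), model_ids)
  if (length(miss))
    stop("missing-model error: no reconstruction for taxon ",
         paste(miss, collapse = ", "))
  models <- models[match(names(a), model_ids)]
  taxa <- names(a)

  lumen_mets <- character()
  for (m in models) {
    met <- m@metabolites
    lumen_mets <- union(lumen_mets,
                        met$id[met$compartment == LUMEN_COMPARTMENT])
  }
  # row layout: per-taxon internal rows, then lumen rows
  row_ids <- character(); row_taxon <- character(); row_comp <- character()
  for (k in seq_along(models)) {
    met <- models[[k]]@metabolites
    internal <- met$compartment != LUMEN_COMPARTMENT
    if (!any(!internal))
      warning("isolated-taxon warning: '", taxa[k],
              "' shares no metabolite with the lumen")
    ids <- paste(taxa[k], met$id[internal], sep = "::")
    row_ids <- c(row_ids, ids)
    row_taxon <- c(row_taxon, rep(taxa[k], sum(internal)))
    row_comp <- c(row_comp, met$compartment[internal])
  }
  n_internal <- length(row_ids)
  row_ids <- c(row_ids, lumen_mets)
  row_taxon <- c(row_taxon, rep(NA_character_, length(lumen_mets)))
  row_comp <- c(row_comp, rep(LUMEN_COMPARTMENT, length(lumen_mets)))
  lumen_row <- stats::setNames(n_internal + seq_along(lumen_mets), lumen_mets)

  ii <- integer(); jj <- integer(); xx <- numeric()
  col_ids <- character(); col_taxon <- character(); col_type <- character()
  col_met <- character(); lb <- numeric(); ub <- numeric()
  biomass_cols <- integer()
  jcur <- 0L
  for (k in seq_along(models)) {
    m <- models[[k]]
    met <- m@metabolites
    is_lumen <- met$compartment == LUMEN_COMPARTMENT
    # map taxon-local met index -> community row
    local_row <- integer(nrow(met))
    local_row[!is_lumen] <- match(paste(taxa[k], met$id[!is_lumen], sep = "::"),
                                  row_ids)
    local_row[is_lumen] <- lumen_row[met$id[is_lumen]]
    Sm <- m@stoichiometry
    for (j in seq_len(ncol(Sm))) {
      jcur <- jcur + 1L
      nz <- which(Sm[, j] != 0)
      coef <- as.numeric(Sm[nz, j])
      scale <- ifelse(is_lumen[nz], a[k], 1)   # abundance-scaled exchanges
      ii <- c(ii, local_row[nz]); jj <- c(jj, rep(jcur, length(nz)))
      xx <- c(xx, coef * scale)
      col_ids <- c(col_ids, paste(taxa[k], m@reactions$id[j], sep = "::"))
      col_taxon <- c(col_taxon, taxa[k])
      kind <- m@reactions$kind[j]
      col_type <- c(col_type, kind)
      exch_met <- if (kind == "exchange") met$id[nz][is_lumen[nz]][1] else NA_character_
      col_met <- c(col_met, exch_met)
      lb <- c(lb, m@reactions$lb[j]); ub <- c(ub, m@reactions$ub[j])
      if (kind == "biomass") {
        biomass_cols[taxa[k]] <- jcur
      }
    }
  }
  diet_cols <- integer()
  for (mm in lumen_mets) {
    jcur <- jcur + 1L
    ii <- c(ii, lumen_row[[mm]]); jj <- c(jj, jcur); xx <- c(xx, -1)
    col_ids <- c(col_ids, paste0("DIET_EX::", mm))
    col_taxon <- c(col_taxon, NA_character_)
    col_type <- c(col_type, "diet")
    col_met <- c(col_met, mm)
    lb <- c(lb, 0); ub <- c(ub, 1000)   # closed until a medium is applied
    diet_cols[mm] <- jcur
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(row_ids), jcur),
                            dimnames = list(row_ids, col_ids))
  methods::new("CommunityModel",
    taxa = taxa,
    abundances = a,
    models = models,
    S = S,
    lb = stats::setNames(lb, col_ids),
    ub = stats::setNames(ub, col_ids),
    reactionInfo = data.frame(id = col_ids, taxon = col_taxon, type = col_type,
                              metabolite = col_met, stringsAsFactors = FALSE),
    metaboliteInfo = data.frame(id = row_ids, taxon = row_taxon,
                                compartment = row_comp,
                                stringsAsFactors = FALSE),
    biomassColumns = biomass_cols,
    dietColumns = diet_cols)
}
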