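#' Construct a taxon metabolic reconstruction
#'
#' Builds a validated \linkS4class{TaxonModel} from a reaction list.  Each
#' reaction is a list with elements \code{id}, \code{stoich} (named numeric,
#' metabolite id -> signed coefficient), \code{kind} and optional \code{lb},
#' \code{ub} (default +/-1000 mmol/(gDW h), the usual constraint-based
#' convention for "unbounded").
#'
#' @param taxonId genus identifier; also the compartment name of internal
#'   metabolites.
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}; compartment is \code{"shared-lumen"},
#'   \code{"external"} or \code{taxonId}.
#' @param reactions list of reaction descriptions (see Details).
#' @return a \linkS4class{TaxonModel}.
#' @examples
#' m <- taxonModel("Acetogen",
#'   metabolites = data.frame(
#'     id = c("glc[u]", "glc[c]"), name = c("glucose", "glucose"),
#'     compartment = c("shared-lumen", "Acetogen")),
#'   reactions = list(
#'     list(id = "EX_glc", stoich = c("glc[u]" = 1, "glc[c]" = -1),
#'          kind = "exchange"),
#'     list(id = "BIOMASS", stoich = c("glc[c]" = -2), kind = "biomass",
#'          lb = 0)))
#' m
#' @export
taxonModel <- function(taxonId, metabolites, reactions) {
  stopifnot(is.character(taxonId), length(taxonId) == 1L)
  metabolites$id <- as.character(metabolites$id)
  metabolites$name <- as.character(metabolites$name)
  metabolites$compartment <- as.character(metabolites$compartment)
  rids <- vapply(reactions, function(r) as.character(r$id), character(1))
  kinds <- vapply(reactions, function(r) as.character(r$kind), character(1))
  lb <- vapply(reactions, function(r) if (is.null(r$lb)) -1000 else as.numeric(r$lb),
               numeric(1))
  ub <- vapply(reactions, function(r) if (is.null(r$ub)) 1000 else as.numeric(r$ub),
               numeric(1))
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoich
    idx <- match(names(st), metabolites$id)
    if (anyNA(idx))
      stop("reaction '", rids[j], "' references undeclared metabolite(s): ",
           paste(names(st)[is.na(idx)], collapse = ", "))
    ii <- c(ii, idx); jj <- c(jj, rep(j, length(st))); xx <- c(xx, as.numeric(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(metabolites), length(reactions)),
                            dimnames = list(metabolites$id, rids))
  bm <- rids[kinds == "biomass"]
  if (length(bm) != 1L)
    stop("exactly one biomass reaction required (found ", length(bm), ")")
  methods::new("TaxonModel",
               taxonId = taxonId,
               metabolites = metabolites,
               reactions = data.frame(id = rids, kind = kinds, lb = lb, ub = ub,
                                      stringsAsFactors = FALSE),
               stoichiometry = S,
               biomassId = bm)
}

.reactionList <- function(model) {
  S <- model@stoichiometry
  lapply(seq_len(ncol(S)), function(j) {
    nz <- which(S[, j] != 0)
    list(id = model@reactions$id[j],
         stoich = stats::setNames(as.numeric(S[nz, j]), rownames(S)[nz]),
         kind = model@reactions$kind[j],
         lb = model@reactions$lb[j],
         ub = model@reactions$ub[j])
  })
}

#' Read a taxon reconstruction from file
#'
#' Two dialects are supported: \code{"toy-json"}, a compact JSON schema
#' used throughout the test suite (top-level keys \code{taxon_id},
#' \code{metabolites}, \code{reactions}; each reaction carries
#' \code{stoich}, \code{lb}, \code{ub}, \code{kind}), and \code{"sbml"},
#' an SBML Level 3 subset with \code{fbc} flux bounds and a flux objective
#' marking the biomass reaction.  Bounds absent from the file default to
#' +/-1000 mmol/(gDW h).
#'
#' @param path file path.
#' @param dialect \code{"toy-json"} or \code{"sbml"}.
#' @return a validated \linkS4class{TaxonModel}.
#' @seealso [writeReconstruction()]
#' @export
readReconstruction <- function(path, dialect = c("toy-json", "sbml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         "toy-json" = .readToyJSON(path),
         "sbml" = .readSBML(path))
}

#' Write a taxon reconstruction to file
#'
#' Inverse of [readReconstruction()]; the round trip is the identity on
#' ids, stoichiometry, bounds and reaction kinds in both dialects.
#'
#' @param model a valid \linkS4class{TaxonModel}.
#' @param path output file path.
#' @param dialect \code{"toy-json"} or \code{"sbml"}.
#' @return \code{path}, invisibly.
#' @export
writeReconstruction <- function(model, path, dialect = c("toy-json", "sbml")) {
  dialect <- match.arg(dialect)
  methods::validObject(model)
  switch(dialect,
         "toy-json" = .writeToyJSON(model, path),
         "sbml" = .writeSBML(model, path))
  invisible(path)
}

.readToyJSON <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("toy-json parse failure in '", path,
                                           "': ", conditionMessage(e)))
  need <- c("taxon_id", "metabolites", "reactions")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("toy-json file '", path, "' lacks element(s): ",
         paste(miss, collapse = ", "))
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment, stringsAsFactors = FALSE)))
  rxns <- lapply(doc$reactions, function(r)
    list(id = r$id, stoich = unlist(r$stoich), kind = r$kind,
         lb = r$lb, ub = r$ub))
  kinds <- vapply(rxns, `[[`, character(1), "kind")
  if (sum(kinds == "biomass") != 1L)
    stop("validation error: reconstruction in '", path,
         "' must declare exactly one biomass reaction")
  model <- taxonModel(doc$taxon_id, mets, rxns)
  methods::validObject(model)
  model
}

.writeToyJSON <- function(model, path) {
  doc <- list(
    taxon_id = model@taxonId,
    metabolites = lapply(seq_len(nrow(model@metabolites)), function(i)
      as.list(model@metabolites[i, c("id", "name", "compartment")])),
    reactions = lapply(.reactionList(model), function(r)
      list(id = r$id, stoich = as.list(r$stoich), lb = r$lb, ub = r$ub,
           kind = r$kind))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# --- SBML Level 3 (+fbc-like bound/objective annotations) subset ---------
# Compartment encoding: the taxon id for internal metabolites, "lumen" for
# shared-lumen, "ext" for external.  Metabolite/reaction ids must be valid
# SBML SIds; ids with other characters belong in the toy-json dialect.

.sbmlSafe <- function(ids) all(grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids))

.writeSBML <- function(model, path) {
  if (!.sbmlSafe(c(model@metabolites$id, model@reactions$id, model@taxonId)))
    stop("SBML dialect requires identifier-safe ids ([A-Za-z_][A-Za-z0-9_]*); ",
         "use the toy-json dialect for free-form ids")
  comp_of <- function(cp) switch(cp,
    "shared-lumen" = "lumen",
    "external" = "ext",
    model@taxonId)
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = model@taxonId)
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(vapply(model@metabolites$compartment, comp_of, character(1))))
    xml2::xml_add_child(comps, "compartment", id = cp, constant = "true")
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model@metabolites))) {
    xml2::xml_add_child(sp, "species",
      id = model@metabolites$id[i],
      name = model@metabolites$name[i],
      compartment = comp_of(model@metabolites$compartment[i]),
      hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
  }
  rx <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in .reactionList(model)) {
    rnode <- xml2::xml_add_child(rx, "reaction", id = r$id,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      kind = r$kind, lowerFluxBound = format(r$lb, digits = 17),
      upperFluxBound = format(r$ub, digits = 17))
    neg <- r$stoich[r$stoich < 0]
    pos <- r$stoich[r$stoich > 0]
    if (length(neg)) {
      rl <- xml2::xml_add_child(rnode, "listOfReactants")
      for (k in seq_along(neg))
        xml2::xml_add_child(rl, "speciesReference", species = names(neg)[k],
          stoichiometry = format(-as.numeric(neg[k]), digits = 17),
          constant = "true")
    }
    if (length(pos)) {
      pl <- xml2::xml_add_child(rnode, "listOfProducts")
      for (k in seq_along(pos))
        xml2::xml_add_child(pl, "speciesReference", species = names(pos)[k],
          stoichiometry = format(as.numeric(pos[k]), digits = 17),
          constant = "true")
    }
  }
  obj <- xml2::xml_add_child(mdl, "listOfObjectives")
  o <- xml2::xml_add_child(obj, "objective", id = "obj", type = "maximize")
  fl <- xml2::xml_add_child(o, "listOfFluxObjectives")
  xml2::xml_add_child(fl, "fluxObjective", reaction = model@biomassId,
                      coefficient = "1")
  xml2::write_xml(doc, path)
}

.readSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("SBML file lacks a <model> element")
  taxon <- xml2::xml_attr(mdl, "id")
  spn <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  if (!length(spn)) stop("SBML model '", taxon, "' declares no species")
  comp_back <- function(cp) {
    if (cp == "lumen") "shared-lumen" else if (cp == "ext") "external" else taxon
  }
  mets <- data.frame(
    id = xml2::xml_attr(spn, "id"),
    name = ifelse(is.na(xml2::xml_attr(spn, "name")),
                  xml2::xml_attr(spn, "id"), xml2::xml_attr(spn, "name")),
    compartment = vapply(xml2::xml_attr(spn, "compartment"), comp_back,
                         character(1)),
    stringsAsFactors = FALSE)
  rnodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  bm_ref <- xml2::xml_attr(
    xml2::xml_find_first(mdl, ".//listOfObjectives//fluxObjective"), "reaction")
  rxns <- lapply(rnodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    lb <- xml2::xml_attr(rn, "lowerFluxBound")
    ub <- xml2::xml_attr(rn, "upperFluxBound")
    kind <- xml2::xml_attr(rn, "kind")
    reac <- xml2::xml_find_all(rn, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(rn, "./listOfProducts/speciesReference")
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      xml2::xml_attr(reac, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "species")))
    if (is.na(kind))
      kind <- if (!is.na(bm_ref) && id == bm_ref) "biomass" else {
        cp <- mets$compartment[match(names(st), mets$id)]
        if (any(cp %in% c("shared-lumen", "external"))) "exchange" else "internal"
      }
    list(id = id, stoich = st, kind = kind,
         lb = if (is.na(lb)) -1000 else as.numeric(lb),
         ub = if (is.na(ub)) 1000 else as.numeric(ub))
  })
  kinds <- vapply(rxns, `[[`, character(1), "kind")
  if (sum(kinds == "biomass") != 1L)
    stop("validation error: SBML model '", taxon,
         "' does not flag exactly one biomass reaction")
  model <- taxonModel(taxon, mets, rxns)
  methods::validObject(model)
  model
}

#' Pool strain reconstructions into a genus pan model
#'
#' Forms the union of the strains' reaction sets.  Reactions are identified
#' by id: duplicates with identical stoichiometry are merged with bounds
#' widened to the interval hull; the same id with different stoichiometry
#' is an error.  The pan biomass reaction is the biomass reaction of the
#' first strain in input order, a deterministic convention (strain biomass
#' compositions differ and there is no canonical merge); other strains'
#' biomass reactions are dropped.  Internal-metabolite compartments are
#' relabelled to \code{taxonId}.
#'
#' Pooling never shrinks the feasible flux set: any flux distribution
#' feasible for one strain (zero elsewhere) remains feasible for the pan
#' model, and pooling a pan model with itself is the identity.
#'
#' @param strainModels list of \linkS4class{TaxonModel}.
#' @param taxonId id for the pooled pan model (e.g. the genus).
#' @return a \linkS4class{TaxonModel}.
#' @export
poolPanModel <- function(strainModels, taxonId) {
  if (!length(strainModels))
    stop("argument error: need at least one strain model")
  for (m in strainModels) stopifnot(methods::is(m, "TaxonModel"))
  relabel <- function(m) {
    mets <- m@metabolites
    mets$compartment[!(mets$compartment %in%
                         c(LUMEN_COMPARTMENT, EXTERNAL_COMPARTMENT))] <- taxonId
    mets
  }
  met_all <- list(); rxn_all <- list(); seen <- new.env(parent = emptyenv())
  conflicts <- character()
  pan_biomass <- NULL
  for (k in seq_along(strainModels)) {
    m <- strainModels[[k]]
    mets <- relabel(m)
    for (i in seq_len(nrow(mets))) {
      id <- mets$id[i]
      if (is.null(met_all[[id]])) {
        met_all[[id]] <- mets[i, ]
      } else if (!identical(met_all[[id]]$compartment, mets$compartment[i])) {
        stop("conflict error: metabolite '", id,
             "' has differing compartments across strains")
      }
    }
    for (r in .reactionList(m)) {
      if (r$kind == "biomass") {
        if (k == 1L) pan_biomass <- r
        next
      }
      prev <- rxn_all[[r$id]]
      if (is.null(prev)) {
        rxn_all[[r$id]] <- r
      } else {
        same <- identical(sort(names(prev$stoich)), sort(names(r$stoich))) &&
          isTRUE(all.equal(prev$stoich[sort(names(prev$stoich))],
                           r$stoich[sort(names(r$stoich))], tolerance = 1e-12))
        if (!same) {
          conflicts <- c(conflicts, r$id)
        } else {
          rxn_all[[r$id]]$lb <- min(prev$lb, r$lb)
          rxn_all[[r$id]]$ub <- max(prev$ub, r$ub)
        }
      }
    }
  }
  if (length(conflicts))
    stop("conflict error: reaction id(s) with differing stoichiometry: ",
         paste(unique(conflicts), collapse = ", "))
  mets <- do.call(rbind, met_all)
  rownames(mets) <- NULL
  rxns <- c(unname(rxn_all), list(pan_biomass))
  taxonModel(taxonId, mets, rxns)
}
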