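# Construction and validation of the reduced kinetic network of cardiac
# central energy metabolism.
#
# A model definition is a structured document (YAML, schema_version 1) with
# sections metabolites / reactions / pools / parameters / substrate_classes.
# `build_reference_model()` loads the shipped calibrated default
# (models/cardiac_reduced_v1.yaml); `build_model()` builds from any parsed
# definition list, validates the schema and stoichiometric bookkeeping, and
# derives the per-substrate ATP yields from the network stoichiometry.

#' Build the shipped reference model of cardiac energy metabolism
#'
#' Loads and validates a model definition document. The default is the
#' calibrated reduced network shipped with the package: one lumped reaction
#' per pathway segment (glucose transport + phosphorylation, glycolysis,
#' lactate exchange + LDH, fatty-acid uptake + activation + beta-oxidation,
#' ketolysis, BCAA transport and oxidation, pyruvate dehydrogenase, TCA
#' cycle, respiratory chain / OXPHOS, hyperbolic ATP demand).
#'
#' @param path Path to a YAML model definition. `NULL` (default) loads the
#'   shipped `cardiac_reduced_v1` model.
#' @return A `cardiocap_model` object; see [build_model()].
#' @export
#' @examples
#' mod <- build_reference_model()
#' mod$atp_yield
build_reference_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "models", "cardiac_reduced_v1.yaml",
                        package = "cardiocap", mustWork = TRUE)
  }
  build_model(yaml::read_yaml(path))
}

#' Build a kinetic network model from a parsed definition
#'
#' Validates the definition (unique ids, positive Km, resolvable references,
#' conserved-pool closure, carbon bookkeeping), compiles each kinetic law
#' into a rate closure, assembles the stoichiometric matrix, and computes
#' the stoichiometric ATP yield of every plasma fuel by solving the internal
#' steady-state balance for a unit uptake flux.
#'
#' @param def A list as returned by [yaml::read_yaml()] on a model document.
#' @return An object of class `cardiocap_model` with elements `metabolites`
#'   (data.frame), `reactions` (named list), `S` (stoichiometric matrix,
#'   metabolites x reactions), `pools`, `parameters`, `atp_yield` (named, ATP
#'   equivalents per molecule of fuel), `o2_per_unit` (O2 consumed per
#'   molecule fully oxidized), `substrate_classes`, and `atp_o2_max`.
#' @export
build_model <- function(def) {
  errs <- character()
  need <- function(cond, msg) if (!cond) errs <<- c(errs, msg)

  need(!is.null(def$metabolites) && length(def$metabolites) > 0, "no metabolites")
  need(!is.null(def$reactions) && length(def$reactions) > 0, "no reactions")

  met <- do.call(rbind, lapply(def$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "cytosol",
               conc0 = as.numeric(m$conc0), boundary = isTRUE(m$boundary),
               carbons = as.numeric(m$carbons %||% 0),
               stringsAsFactors = FALSE)
  }))
  need(!anyDuplicated(met$id), "duplicate metabolite ids")
  need(all(met$conc0 >= 0), "negative conc0")
  need(all(met$compartment %in% c("plasma", "cytosol", "mitochondria")),
       "invalid compartment")
  if (length(errs)) stop("model validation failed: ", paste(errs, collapse = "; "),
                         call. = FALSE)

  mids <- met$id
  rxns <- list()
  for (r in def$reactions) {
    rid <- r$id
    st <- unlist(r$stoich)
    need(length(st) > 0, paste0(rid, ": empty stoichiometry"))
    bad <- setdiff(names(st), mids)
    need(length(bad) == 0, paste0(rid, ": unknown metabolites ", paste(bad, collapse = ",")))
    law <- r$law
    need(!is.null(law$form) && law$form %in% .law_forms,
         paste0(rid, ": unknown law form"))
    need(is.numeric(law$vmax) && law$vmax >= 0, paste0(rid, ": vmax must be >= 0"))
    km <- unlist(law$km %||% list())
    need(all(km > 0), paste0(rid, ": all km must be > 0"))
    badk <- setdiff(names(km), names(st))
    need(length(badk) == 0, paste0(rid, ": km references non-participant ", paste(badk, collapse = ",")))
    for (m in law$modifiers %||% list()) {
      need(m$id %in% mids, paste0(rid, ": unknown modifier ", m$id))
      need(m$type %in% c("activator", "inhibitor"), paste0(rid, ": bad modifier type"))
      need(is.numeric(m$k_eff) && m$k_eff > 0, paste0(rid, ": modifier k_eff must be > 0"))
    }
    rxns[[rid]] <- list(
      id = rid, stoich = st, law = law,
      proteins = as.character(unlist(r$proteins %||% character())),
      pathway = r$pathway %||% "transport",
      insulin_regulated = isTRUE(r$insulin_regulated))
  }
  need(!anyDuplicated(names(rxns)), "duplicate reaction ids")
  if (length(errs)) stop("model validation failed: ", paste(errs, collapse = "; "),
                         call. = FALSE)

  # stoichiometric matrix (metabolites x reactions)
  S <- matrix(0, nrow(met), length(rxns), dimnames = list(mids, names(rxns)))
  for (rid in names(rxns)) S[names(rxns[[rid]]$stoich), rid] <- rxns[[rid]]$stoich

  # conserved pools must be closed by every reaction
  pools <- lapply(def$pools %||% list(), function(p) {
    bad <- setdiff(p$members, mids)
    need(length(bad) == 0, paste0("pool ", p$id, ": unknown members"))
    need(is.numeric(p$total) && p$total > 0, paste0("pool ", p$id, ": total must be > 0"))
    p
  })
  if (length(errs)) stop("model validation failed: ", paste(errs, collapse = "; "),
                         call. = FALSE)
  for (p in pools) {
    drift <- colSums(S[p$members, , drop = FALSE])
    if (any(abs(drift) > 1e-9))
      stop("model error: pool '", p$id, "' not conserved by reaction(s) ",
           paste(names(rxns)[abs(drift) > 1e-9], collapse = ","), call. = FALSE)
    tot0 <- sum(met$conc0[met$id %in% p$members])
    if (abs(tot0 - p$total) > 1e-9)
      stop("model error: pool '", p$id, "' initial concentrations sum to ",
           tot0, ", not the declared total ", p$total, call. = FALSE)
  }

  # carbon bookkeeping: each reaction may release CO2 (untracked) but never
  # create carbon
  crel <- -as.numeric(met$carbons %*% S)
  if (any(crel < -1e-9))
    stop("model error: carbon created by reaction(s) ",
         paste(names(rxns)[crel < -1e-9], collapse = ","), call. = FALSE)

  model <- structure(list(
    name = def$name %||% "unnamed",
    schema_version = def$schema_version %||% 1,
    metabolites = met,
    reactions = rxns,
    S = S,
    pools = pools,
    parameters = def$parameters %||% list(),
    substrate_classes = lapply(def$substrate_classes %||% list(), unlist)
  ), class = "cardiocap_model")

  model$rate_fns <- lapply(rxns, function(r) .compile_law(r$law, r$stoich))
  model$demand_id <- names(rxns)[vapply(rxns, function(r) r$law$form == "load-hyperbolic",
                                        logical(1))]
  if (length(model$demand_id) != 1)
    stop("model error: exactly one load-hyperbolic ATP demand reaction required",
         call. = FALSE)

  y <- .atp_yields(model)
  model$atp_yield <- y$yield
  model$o2_per_unit <- y$o2
  ratio <- y$yield / y$o2
  model$atp_o2_max <- if (all(!is.finite(ratio))) NA_real_ else max(ratio[is.finite(ratio)])
  model
}

#' Per-substrate stoichiometric ATP yields
#'
#' For each plasma fuel, fixes a unit uptake flux through its exchange
#' reaction, removes the exchange reactions of all other fuels, and solves
#' the internal-species steady-state balance S_int v = 0 for the remaining
#' fluxes; the demand flux of that solution is the ATP yield per molecule,
#' and 2 x the O2 stoichiometry of the respiratory flux gives O2 per
#' molecule. Yields are therefore properties of the shipped stoichiometry,
#' never hard-coded constants.
#' @noRd
.atp_yields <- function(model) {
  met <- model$metabolites
  S <- model$S
  internal <- met$id[!met$boundary]
  fuels <- setdiff(met$id[met$boundary], .o2_ids(model))
  # exchange reaction of each fuel: the reaction(s) consuming that boundary species
  exch <- lapply(fuels, function(f) colnames(S)[S[f, ] != 0])
  names(exch) <- fuels

  yield <- o2 <- setNames(rep(NA_real_, length(fuels)), fuels)
  o2_id <- .o2_ids(model)
  for (f in fuels) {
    up <- exch[[f]][1]
    drop <- setdiff(unique(unlist(exch[setdiff(fuels, f)])), up)
    keep <- setdiff(colnames(S), c(up, drop))
    A <- S[internal, keep, drop = FALSE]
    b <- -S[internal, up] / abs(S[f, up])  # unit uptake of one molecule of f
    sol <- stats::lsfit(A, b, intercept = FALSE)
    if (max(abs(sol$residuals)) > 1e-8)
      stop("model error: no consistent oxidation route for fuel '", f, "'",
           call. = FALSE)
    v <- setNames(sol$coefficients, keep)
    yield[f] <- v[model$demand_id]
    o2_use <- if (length(o2_id)) -sum(S[o2_id, keep, drop = FALSE] %*% v) else NA_real_
    o2[f] <- o2_use
  }
  list(yield = yield, o2 = o2)
}

.o2_ids <- function(model) {
  intersect(c("o2_e", "o2"), model$metabolites$id)
}

#' @export
print.cardiocap_model <- function(x, ...) {
  met <- x$metabolites
  cat("<cardiocap_model> ", x$name, "\n", sep = "")
  cat("  ", nrow(met), " metabolites (", sum(met$boundary), " plasma-clamped), ",
      length(x$reactions), " reactions, ", length(x$pools), " conserved pools\n", sep = "")
  cat("  ATP yields (per molecule): ",
      paste(sprintf("%s=%.1f", names(x$atp_yield), x$atp_yield), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Initial concentrations of a model, optionally overridden by a plasma profile
#' @noRd
.initial_conc <- function(model, profile = NULL) {
  conc <- setNames(model$metabolites$conc0, model$metabolites$id)
  if (!is.null(profile)) {
    bmap <- .profile_boundary_map(profile)
    bmap <- bmap[names(bmap) %in% names(conc)]
    conc[names(bmap)] <- bmap
  }
  conc
}
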