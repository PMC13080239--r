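# Plasma metabolite profiles: the boundary conditions of every simulation.

.profile_fields <- c("glucose", "fatty_acids", "lactate", "valine", "leucine",
                     "isoleucine", "bhb", "acac")

#' Construct a plasma profile
#'
#' A plasma profile fixes the clamped boundary concentrations of the eight
#' energy-delivering plasma species (mM) plus insulin (pM) and
#' catecholamines (nM). Two physiological built-ins are provided by
#' [plasma_profile_builtin()]: an overnight-fasted state (high fatty acids,
#' moderate glucose) and a postprandial state (high glucose and lactate, low
#' fatty acids, no ketones, high insulin).
#'
#' @param glucose,fatty_acids,lactate,valine,leucine,isoleucine,bhb,acac
#'   Plasma concentrations in mM; all must be >= 0.
#' @param insulin Insulin in pM.
#' @param catecholamines Catecholamines in nM (accepted for completeness; the
#'   reduced network applies no catecholamine regulation, see the vignette).
#' @param label Free-text label.
#' @return A `plasma_profile` object (named list).
#' @export
#' @examples
#' plasma_profile_builtin("fasted")
plasma_profile <- function(glucose, fatty_acids, lactate, valine, leucine,
                           isoleucine, bhb, acac, insulin, catecholamines = 0.75,
                           label = "custom") {
  p <- list(glucose = glucose, fatty_acids = fatty_acids, lactate = lactate,
            valine = valine, leucine = leucine, isoleucine = isoleucine,
            bhb = bhb, acac = acac, insulin = insulin,
            catecholamines = catecholamines, label = label)
  num <- unlist(p[c(.profile_fields, "insulin", "catecholamines")])
  if (any(!is.finite(num)) || any(num < 0))
    stop("plasma profile values must be finite and >= 0", call. = FALSE)
  structure(p, class = "plasma_profile")
}

#' Built-in physiological plasma profiles
#'
#' @param state `"fasted"` (postabsorptive, overnight fasted) or
#'   `"postprandial"` (after meal).
#' @return A [plasma_profile()].
#' @export
plasma_profile_builtin <- function(state = c("fasted", "postprandial")) {
  state <- match.arg(state)
  if (state == "fasted") {
    plasma_profile(glucose = 5.8, fatty_acids = 0.5, lactate = 0.8,
                   valine = 0.2, leucine = 0.15, isoleucine = 0.06,
                   bhb = 0.08, acac = 0.04, insulin = 100,
                   catecholamines = 0.75, label = "fasted")
  } else {
    plasma_profile(glucose = 7.8, fatty_acids = 0.1, lactate = 2.0,
                   valine = 0.4, leucine = 0.4, isoleucine = 0.2,
                   bhb = 0, acac = 0, insulin = 600,
                   catecholamines = 0.75, label = "postprandial")
  }
}

#' Merge an individual plasma panel into a default profile
#'
#' Per-sample measured metabolites override the matching default fields;
#' anything the panel does not supply is kept from `defaults`. Fields the
#' model has no substrate for (e.g. plasma triglycerides) are dropped with a
#' message. Used for individualized capacity scans.
#'
#' @param panel Named list / vector of measured plasma values (mM; `insulin`
#'   in pM if present).
#' @param defaults A [plasma_profile()] supplying unmeasured fields.
#' @param quiet Suppress per-field merge messages.
#' @return A merged [plasma_profile()].
#' @export
merge_plasma_panel <- function(panel, defaults, quiet = FALSE) {
  stopifnot(inherits(defaults, "plasma_profile"))
  panel <- as.list(panel)
  if (length(panel) == 0 && !quiet)
    warning("empty plasma panel; using defaults '", defaults$label, "'", call. = FALSE)
  out <- defaults
  known <- c(.profile_fields, "insulin", "catecholamines")
  for (nm in names(panel)) {
    if (!nm %in% known) {
      if (!quiet) message("plasma panel field '", nm, "' is not a model substrate; ignored")
      next
    }
    val <- as.numeric(panel[[nm]])
    if (!is.finite(val) || val < 0)
      stop("plasma panel field '", nm, "' must be finite and >= 0", call. = FALSE)
    if (!quiet) message("plasma panel: ", nm, " ", out[[nm]], " -> ", val)
    out[[nm]] <- val
  }
  out$label <- paste0(defaults$label, "+panel")
  out
}

# profile field -> boundary metabolite id of the reduced network
.profile_boundary_map <- function(profile) {
  c(glc_e = profile$glucose, ffa_e = profile$fatty_acids, lac_e = profile$lactate,
    val_e = profile$valine, leu_e = profile$leucine, ile_e = profile$isoleucine,
    bhb_e = profile$bhb, acac_e = profile$acac)
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat("<plasma_profile> ", x$label, "\n", sep = "")
  v <- unlist(x[.profile_fields])
  cat("  ", paste(sprintf("%s=%g mM", names(v), v), collapse = ", "), "\n", sep = "")
  cat("  insulin=", x$insulin, " pM, catecholamines=", x$catecholamines, " nM\n", sep = "")
  invisible(x)
}
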