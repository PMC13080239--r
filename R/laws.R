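# Kinetic rate laws for the reduced cardiac network.
#
# Concentrations are mM, fluxes mM * min^-1 per g wet tissue. Each law is
# "compiled" at model-build time into a closure taking the full named
# concentration vector plus a vmax multiplier (the proteome scaling factor),
# so the ODE right-hand side stays cheap.

.law_forms <- c("irreversible-MM", "reversible-MM", "mass-action",
                "facilitated-transport", "load-hyperbolic")

#' Evaluate regulatory modifier terms
#'
#' Activators contribute C/(C + k), inhibitors k/(k + C); the product of all
#' modifier terms multiplies the core rate.
#' @noRd
.modifier_factor <- function(modifiers, conc) {
  f <- 1
  for (m in modifiers) {
    x <- conc[[m$id]]
    f <- f * if (m$type == "activator") x / (x + m$k_eff) else m$k_eff / (m$k_eff + x)
  }
  f
}

#' Compile one kinetic law into a rate closure
#'
#' @param law list with `form`, `vmax`, `km` (named), optional `keq`,
#'   optional `modifiers` (list of lists with id/type/k_eff).
#' @param stoich named signed stoichiometry of the parent reaction.
#' @return function(conc, vscale = 1) -> rate (mM/min).
#' @noRd
.compile_law <- function(law, stoich) {
  form <- law$form
  km <- unlist(law$km %||% list())
  modifiers <- law$modifiers %||% list()
  vmax <- law$vmax
  subs <- names(stoich)[stoich < 0]
  prods <- names(stoich)[stoich > 0]

  if (form %in% c("irreversible-MM", "facilitated-transport")) {
    km_s <- km[names(km) %in% subs]
    ids <- names(km_s)
    function(conc, vscale = 1) {
      s <- conc[ids]
      rate <- vmax * vscale * prod(s / (s + km_s))
      if (length(modifiers)) rate <- rate * .modifier_factor(modifiers, conc)
      rate
    }
  } else if (form == "reversible-MM") {
    # Convenience-kinetics style: saturating in both directions, equilibrium
    # where prod(P/KmP) = keq * prod(S/KmS); keq is Km-scaled (dimensionless).
    keq <- law$keq %||% 1
    km_s <- km[names(km) %in% subs]
    km_p <- km[names(km) %in% prods]
    ids_s <- names(km_s); ids_p <- names(km_p)
    function(conc, vscale = 1) {
      fs <- prod(conc[ids_s] / km_s)
      fp <- prod(conc[ids_p] / km_p)
      rate <- vmax * vscale * (fs - fp / keq) / (1 + fs + fp)
      if (length(modifiers)) rate <- rate * .modifier_factor(modifiers, conc)
      rate
    }
  } else if (form == "mass-action") {
    function(conc, vscale = 1) {
      rate <- vmax * vscale * prod(conc[subs])
      if (length(modifiers)) rate <- rate * .modifier_factor(modifiers, conc)
      rate
    }
  } else if (form == "load-hyperbolic") {
    # ATP demand: v = load * ATP / (ATP + km_atp). `vmax` carries the load
    # scale; it is ramped by the load-scan machinery, never proteome-scaled.
    km_atp <- km[["atp"]]
    function(conc, vscale = 1) {
      a <- conc[["atp"]]
      vmax * vscale * a / (a + km_atp)
    }
  } else {
    stop("unknown kinetic law form: ", form, call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
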