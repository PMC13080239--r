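# Rate evaluation and steady-state solution of the reduced network.
#
# Internal species are integrated with a stiff solver (deSolve::lsoda) to a
# fixed horizon with an explicit residual test; if integration alone does
# not reach the residual tolerance, a damped Newton iteration is run from
# the integration endpoint. Plasma (boundary) species are clamped
# throughout. Deterministic initial conditions come from the model's conc0.

#' Evaluate all reaction rates at a given metabolic state
#'
#' Applies each reaction's kinetic law at the supplied concentrations.
#' Insulin acts as a single multiplier `1 + a_ins * I / (I + K_ins)` on the
#' vmax of insulin-regulated reactions (glucose transport in the shipped
#' model). Catecholamines are accepted for interface completeness but the
#' reduced network applies no catecholamine term (multiplier 1).
#'
#' @param model A `cardiocap_model`.
#' @param conc Named concentration vector (mM) covering every metabolite.
#' @param insulin Insulin (pM), >= 0.
#' @param catecholamine Catecholamines (nM), >= 0; currently inert.
#' @param vscale Optional named per-reaction vmax multipliers (proteome
#'   scaling); unnamed reactions default to 1.
#' @param load Optional ATP demand scale (mM/min) applied to the demand
#'   reaction; defaults to the model's resting demand `load_rest`.
#' @return Named flux vector (mM/min).
#' @export
evaluate_rates <- function(model, conc, insulin = 0, catecholamine = 0,
                           vscale = NULL, load = NULL) {
  stopifnot(inherits(model, "cardiocap_model"))
  missing_ids <- setdiff(model$metabolites$id, names(conc))
  if (length(missing_ids))
    stop("missing concentration for: ", paste(missing_ids, collapse = ","), call. = FALSE)
  if (any(conc < 0)) stop("negative concentration supplied", call. = FALSE)
  if (insulin < 0 || catecholamine < 0)
    stop("hormone values must be >= 0", call. = FALSE)
  vs <- .resolve_vscale(model, vscale, insulin, load)
  .rates(model, conc, vs)
}

# full per-reaction vmax multiplier: proteome scale x insulin x load override
.resolve_vscale <- function(model, vscale, insulin, load) {
  rids <- names(model$reactions)
  vs <- setNames(rep(1, length(rids)), rids)
  if (!is.null(vscale)) {
    bad <- setdiff(names(vscale), rids)
    if (length(bad)) stop("vscale names unknown: ", paste(bad, collapse = ","), call. = FALSE)
    vs[names(vscale)] <- vscale
  }
  ins <- model$parameters$insulin %||% list(a_ins = 1, k_ins = 200)
  fac <- 1 + ins$a_ins * insulin / (insulin + ins$k_ins)
  reg <- vapply(model$reactions, function(r) r$insulin_regulated, logical(1))
  vs[reg] <- vs[reg] * fac
  if (!is.null(load)) vs[model$demand_id] <- load
  vs
}

.rates <- function(model, conc, vs) {
  fns <- model$rate_fns
  out <- numeric(length(fns))
  for (i in seq_along(fns)) out[i] <- fns[[i]](conc, vs[i])
  names(out) <- names(fns)
  out
}

#' Solve the network to steady state under a plasma profile and ATP load
#'
#' @param model A `cardiocap_model` (possibly a proteome-scaled sample
#'   instance model).
#' @param profile A [plasma_profile()] clamping the boundary species.
#' @param load ATP demand scale (mM/min) of the hyperbolic demand law.
#' @param vscale Optional named per-reaction vmax multipliers.
#' @param init Optional named initial concentrations for internal species
#'   (warm start); defaults to the model's conc0.
#' @param boundary_override Optional named concentrations for boundary
#'   species, applied after the profile (used by titrations).
#' @param tol_ss Steady-state residual tolerance, max |dC/dt| (mM/min).
#' @param horizon Integration horizon (min).
#' @return A `cardiocap_steady_state`: list with `conc` (full vector, mM),
#'   `flux` (mM/min), `residual`, `converged`, `load`, `atp_production`
#'   (net ATP-producing flux excluding the demand reaction) and
#'   `o2_consumption`.
#' @export
solve_steady_state <- function(model, profile, load, vscale = NULL, init = NULL,
                               boundary_override = NULL,
                               tol_ss = 1e-6, horizon = 60) {
  stopifnot(inherits(model, "cardiocap_model"), load >= 0)
  conc <- .initial_conc(model, profile)
  internal <- model$metabolites$id[!model$metabolites$boundary]
  if (!is.null(boundary_override)) {
    bad <- setdiff(names(boundary_override), setdiff(names(conc), internal))
    if (length(bad)) stop("boundary_override names must be boundary species: ",
                          paste(bad, collapse = ","), call. = FALSE)
    conc[names(boundary_override)] <- boundary_override
  }
  if (!is.null(init)) {
    init <- init[names(init) %in% internal]
    conc[names(init)] <- init
  }
  insulin <- if (is.null(profile)) 0 else profile$insulin
  vs <- .resolve_vscale(model, vscale, insulin, load)

  # eliminate one member per conserved pool: its concentration follows from
  # the pool total, which removes the singular directions of the Jacobian
  dep <- vapply(model$pools, function(p) p$members[length(p$members)], character(1))
  free <- setdiff(internal, dep)
  Sfree <- model$S[free, , drop = FALSE]

  full <- conc
  complete <- function(full) {
    for (p in model$pools) {
      d <- p$members[length(p$members)]
      full[d] <- max(p$total - sum(full[setdiff(p$members, d)]), 0)
    }
    full
  }
  rhs <- function(t, y, p) {
    full[free] <- pmax(y, 0)
    full <- complete(full)
    list(as.numeric(Sfree %*% .rates(model, full, vs)))
  }
  y <- conc[free]
  residual_of <- function(y) {
    full[free] <- pmax(y, 0)
    full <- complete(full)
    max(abs(Sfree %*% .rates(model, full, vs)))
  }

  checkpoints <- horizon * c(0.05, 0.15, 0.35, 0.65, 1)
  t0 <- 0
  res <- residual_of(y)
  min_seen <- 0
  # near a steady state (warm start along a continuation) Newton alone is
  # much cheaper than stiff integration; fall through to integration if it
  # does not reach tolerance
  if (res > tol_ss && res < 20) {
    ns <- .newton_polish(y, free, full, Sfree, model, vs,
                         min(tol_ss * 1e-4, 1e-10), complete)
    if (ns$residual <= tol_ss) { y <- ns$y; res <- ns$residual }
  }
  for (tc in checkpoints) {
    if (res <= tol_ss) break
    sol <- deSolve::lsoda(y, c(t0, tc), rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    y <- sol[nrow(sol), -1]
    min_seen <- min(min_seen, y)
    y <- pmax(y, 0)
    t0 <- tc
    res <- residual_of(y)
  }
  if (min_seen < -1e-9)
    warning("internal concentration dipped to ", signif(min_seen, 3),
            " during integration; clipped to 0", call. = FALSE)

  # polish to well below tol_ss so downstream attribution sums are clean
  ns <- .newton_polish(y, free, full, Sfree, model, vs,
                       min(tol_ss * 1e-4, 1e-10), complete)
  if (ns$residual < res) { y <- ns$y; res <- ns$residual }

  full[free] <- pmax(y, 0)
  full <- complete(full)
  flux <- .rates(model, full, vs)
  structure(list(
    conc = full, flux = flux, residual = res, converged = res <= tol_ss,
    load = load, tol_ss = tol_ss,
    atp_production = .atp_production(model, flux),
    o2_consumption = .o2_consumption(model, flux)
  ), class = "cardiocap_steady_state")
}

# damped Newton on the reduced internal balance, numeric forward-difference
# Jacobian (pool-dependent species eliminated, so J is generically regular)
.newton_polish <- function(y, free, full, Sfree, model, vs, tol_ss,
                           complete, max_iter = 50) {
  f <- function(y) {
    full[free] <- pmax(y, 0)
    full <- complete(full)
    as.numeric(Sfree %*% .rates(model, full, vs))
  }
  n <- length(y)
  fy <- f(y)
  for (it in seq_len(max_iter)) {
    if (max(abs(fy)) <= tol_ss) break
    J <- matrix(0, n, n)
    h <- pmax(abs(y), 1e-4) * 1e-7
    for (j in seq_len(n)) {
      yp <- y; yp[j] <- yp[j] + h[j]
      J[, j] <- (f(yp) - fy) / h[j]
    }
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- pmax(y + lambda * step, 0)
      fc <- f(cand)
      if (max(abs(fc)) < max(abs(fy)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (max(abs(fc)) >= max(abs(fy))) break
    y <- cand; fy <- fc
  }
  list(y = y, residual = max(abs(fy)))
}

# net ATP-producing flux, demand excluded: sum_r stoich(atp, r) * v_r
.atp_production <- function(model, flux) {
  if (!"atp" %in% rownames(model$S)) return(NA_real_)
  keep <- setdiff(colnames(model$S), model$demand_id)
  sum(model$S["atp", keep] * flux[keep])
}

.o2_consumption <- function(model, flux) {
  o2 <- .o2_ids(model)
  if (!length(o2)) return(NA_real_)
  -sum(model$S[o2, , drop = FALSE] %*% flux)
}

#' Stoichiometric balance report for a converged steady state
#'
#' An independent check, not used by the solver: recomputes S v for every
#' internal metabolite at the reported state and the drift of every
#' conserved moiety pool relative to its declared total.
#'
#' @param model A `cardiocap_model`.
#' @param state A `cardiocap_steady_state`.
#' @return List with `species` (data.frame id, dcdt), `max_residual`, and
#'   `pools` (data.frame pool, total, observed, drift).
#' @export
check_balance <- function(model, state) {
  internal <- model$metabolites$id[!model$metabolites$boundary]
  dcdt <- as.numeric(model$S[internal, , drop = FALSE] %*% state$flux)
  pools <- do.call(rbind, lapply(model$pools, function(p) {
    obs <- sum(state$conc[p$members])
    data.frame(pool = p$id, total = p$total, observed = obs,
               drift = obs - p$total, stringsAsFactors = FALSE)
  }))
  list(species = data.frame(id = internal, dcdt = dcdt, stringsAsFactors = FALSE),
       max_residual = max(abs(dcdt)),
       pools = pools %||% data.frame())
}

#' @export
print.cardiocap_steady_state <- function(x, ...) {
  cat("<steady state> load=", x$load, " mM/min, converged=", x$converged,
      ", residual=", signif(x$residual, 3), "\n", sep = "")
  cat("  ATP production ", signif(x$atp_production, 4), " mM/min, O2 ",
      signif(x$o2_consumption, 4), " mM/min\n", sep = "")
  invisible(x)
}
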