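# Metabolic readouts per sample: substrate-utilization capacities, ATP
# production capacity under a stepwise load ramp, ATP/O2, substrate
# contribution shares, and whole-heart scaling.

# accept either a bare model or a proteome-scaled sample instance
.as_model_scale <- function(x) {
  if (inherits(x, "cardiocap_instance")) list(model = x$model, vscale = x$scale)
  else if (inherits(x, "cardiocap_model")) list(model = x, vscale = NULL)
  else stop("expected a cardiocap_model or cardiocap_instance", call. = FALSE)
}

#' ATP-equivalent substrate contributions at a steady state
#'
#' Attributes the total ATP production to the plasma fuels: each substrate
#' class contributes its net uptake flux times the network's stoichiometric
#' ATP yield per molecule. Glycolytic and oxidative glucose ATP are both
#' attributed to glucose; a net lactate export therefore shows up as a
#' negative lactate contribution. By linearity of the steady-state balance
#' the contributions sum to the total ATP production.
#'
#' @param state A converged `cardiocap_steady_state`.
#' @param model The `cardiocap_model` the state was solved on.
#' @return Named vector of ATP-equivalent rates (mM/min), one per substrate
#'   class (`glucose`, `ffa`, `lactate`, `ketones`, `bcaa`).
#' @export
substrate_contributions <- function(state, model) {
  stopifnot(inherits(state, "cardiocap_steady_state"))
  uptake <- -as.numeric(model$S %*% state$flux)  # >0 where consumed
  names(uptake) <- rownames(model$S)
  vapply(model$substrate_classes, function(members) {
    sum(uptake[members] * model$atp_yield[members])
  }, numeric(1))
}

#' Stepwise ATP load ramp to the maximal production capacity
#'
#' Starting from a small fraction of the resting demand, the load scale of
#' the hyperbolic demand law is increased multiplicatively; the network is
#' re-solved to steady state at each load (warm-started from the previous
#' one). The ramp stops when the relative gain in ATP production over one
#' step falls below `tol_plateau`, or at the last converged load if a step
#' fails to converge.
#'
#' @param instance A `cardiocap_model` or `cardiocap_instance`.
#' @param profile A [plasma_profile()].
#' @param load0 Initial load (mM/min); default 10% of the model's resting
#'   demand `load_rest`.
#' @param step Multiplicative load increment (> 1).
#' @param max_steps Maximum ramp length.
#' @param tol_plateau Relative production-gain threshold declaring the
#'   plateau.
#' @return A `cardiocap_load_scan`: data.frame `scan` (load, load_rel,
#'   atp_production, o2_consumption, atp_o2, one share column per
#'   substrate), `max_atp`, `atp_o2_at_max`, `converged_at`, `plateau`.
#' @export
atp_load_scan <- function(instance, profile, load0 = NULL, step = 1.25,
                          max_steps = 60, tol_plateau = 1e-3) {
  ms <- .as_model_scale(instance)
  model <- ms$model
  stopifnot(step > 1, max_steps >= 2)
  load_rest <- model$parameters$load_rest %||% 1
  if (is.null(load0)) load0 <- 0.1 * load_rest
  stopifnot(load0 > 0)

  rows <- list()
  init <- NULL
  prev_atp <- NA_real_
  load <- load0
  plateau <- FALSE
  classes <- names(model$substrate_classes)
  for (i in seq_len(max_steps)) {
    ss <- solve_steady_state(model, profile, load, vscale = ms$vscale, init = init)
    if (!ss$converged) {
      if (i == 1) stop("load ramp failed to converge at the initial load; ",
                       "model and profile are incompatible", call. = FALSE)
      warning("load ramp stopped: non-convergence at load ", signif(load, 4),
              "; reporting previous plateau", call. = FALSE)
      break
    }
    contrib <- substrate_contributions(ss, model)
    tot <- ss$atp_production
    # past the capacity plateau production can fall as ATP collapses; such a
    # point is not part of the reported (non-decreasing) ramp
    declining <- !is.na(prev_atp) && tot < prev_atp
    if (!declining) {
      shares <- if (tot > 0) contrib / tot else rep(NA_real_, length(contrib))
      rows[[length(rows) + 1]] <- c(load = load, load_rel = load / load_rest,
                   atp_production = tot, o2_consumption = ss$o2_consumption,
                   atp_o2 = if (ss$o2_consumption > 0) tot / ss$o2_consumption else NA_real_,
                   setNames(shares, paste0("share_", classes)))
    }
    internal <- model$metabolites$id[!model$metabolites$boundary]
    init <- ss$conc[internal]
    if (!is.na(prev_atp) && prev_atp > 0 &&
        (tot - prev_atp) / prev_atp < tol_plateau) {
      plateau <- TRUE
      break
    }
    prev_atp <- tot
    load <- load * step
  }
  scan <- as.data.frame(do.call(rbind, rows))
  last <- nrow(scan)
  structure(list(
    scan = scan,
    max_atp = scan$atp_production[last],
    atp_o2_at_max = scan$atp_o2[last],
    converged_at = scan$load[last],
    plateau = plateau,
    profile = profile$label
  ), class = "cardiocap_load_scan")
}

#' Maximal utilization capacity of one substrate class by titration
#'
#' Raises the plasma concentration of one substrate class over a titration
#' grid while clamping all other plasma species at the base profile, under
#' a high ancillary ATP demand (so uptake, not demand, limits), and reports
#' the maximal steady-state uptake flux of the titrated class. Ketone
#' bodies are titrated jointly at a fixed 2:1 bhb:acac ratio; the three
#' BCAAs jointly in their base-profile proportions.
#'
#' @param instance A `cardiocap_model` or `cardiocap_instance`.
#' @param substrate One of `"glucose"`, `"ffa"`, `"lactate"`, `"ketones"`,
#'   `"bcaa"`.
#' @param base Base [plasma_profile()] (default: fasted built-in).
#' @param n_grid Number of titration points (geometric from the base value
#'   to `max_fold` x base; linear 0-10 mM when the base concentration is 0).
#' @param max_fold Upper end of the titration in multiples of the base.
#' @param demand_fold Ancillary ATP demand in multiples of resting demand.
#' @param grid Optional explicit vector of total class concentrations (mM)
#'   overriding the automatic titration grid.
#' @return List with `capacity` (mM of substrate /min), `grid` (data.frame
#'   conc, uptake), `plateau` (logical: relative gain over the last two grid
#'   points < 1e-3).
#' @export
substrate_capacity <- function(instance, substrate, base = plasma_profile_builtin("fasted"),
                               n_grid = 12, max_fold = 50, demand_fold = 10,
                               grid = NULL) {
  ms <- .as_model_scale(instance)
  model <- ms$model
  members <- model$substrate_classes[[substrate]]
  if (is.null(members))
    stop("unknown substrate class: ", substrate, call. = FALSE)
  conc_base <- .initial_conc(model, base)
  base_vals <- conc_base[members]
  base_tot <- sum(base_vals)
  if (is.null(grid)) {
    grid <- if (base_tot > 0)
      exp(seq(log(base_tot), log(max_fold * base_tot), length.out = n_grid))
    else seq(10 / n_grid, 10, length.out = n_grid)
  } else n_grid <- length(grid)
  prop <- if (substrate == "ketones") setNames(c(2, 1) / 3, members)  # bhb:acac 2:1
          else if (base_tot > 0) base_vals / base_tot
          else setNames(rep(1 / length(members), length(members)), members)

  load <- demand_fold * (model$parameters$load_rest %||% 1)
  uptakes <- rep(NA_real_, n_grid)
  init <- NULL
  internal <- model$metabolites$id[!model$metabolites$boundary]
  for (i in seq_len(n_grid)) {
    ss <- tryCatch(solve_steady_state(model, base, load, vscale = ms$vscale,
                                      init = init,
                                      boundary_override = grid[i] * prop),
                   error = function(e) NULL)
    if (is.null(ss) || !ss$converged) {
      warning("titration point ", signif(grid[i], 4), " mM skipped (non-convergence)",
              call. = FALSE)
      next
    }
    up <- -as.numeric(model$S[members, , drop = FALSE] %*% ss$flux)
    uptakes[i] <- sum(up)
    init <- ss$conc[internal]
  }
  if (all(is.na(uptakes)))
    stop("substrate_capacity: no titration point converged", call. = FALSE)
  ok <- which(!is.na(uptakes))
  cap <- max(uptakes[ok])
  lastok <- utils::tail(ok, 2)
  plateau <- length(lastok) == 2 &&
    abs(uptakes[lastok[2]] - uptakes[lastok[1]]) <
      1e-3 * max(abs(uptakes[lastok[1]]), .Machine$double.eps)
  list(capacity = cap,
       grid = data.frame(conc = grid, uptake = uptakes),
       plateau = plateau, substrate = substrate)
}

#' Whole-heart capacity from a per-gram capacity and cardiac mass
#'
#' @param per_gram Capacity per g wet tissue (mM/min/g).
#' @param heart_mass_mg Heart mass in mg (> 0).
#' @return Whole-heart capacity (mmol-equivalent scale: mM/min x g).
#' @export
whole_heart_capacity <- function(per_gram, heart_mass_mg) {
  if (any(heart_mass_mg <= 0)) stop("heart mass must be > 0", call. = FALSE)
  per_gram * heart_mass_mg / 1000
}

#' ATP load scan under an individualized plasma panel
#'
#' Merges a per-sample measured plasma panel into a default profile (fields
#' the panel does not supply are kept at the default; non-substrate fields
#' such as triglycerides are dropped with a message) and runs
#' [atp_load_scan()] under the merged profile.
#'
#' @param instance A `cardiocap_model` or `cardiocap_instance`.
#' @param panel Named list/vector of measured plasma values.
#' @param defaults Default [plasma_profile()].
#' @param ... Passed to [atp_load_scan()].
#' @export
individualized_scan <- function(instance, panel, defaults = plasma_profile_builtin("fasted"),
                                ...) {
  prof <- merge_plasma_panel(panel, defaults, quiet = FALSE)
  atp_load_scan(instance, prof, ...)
}

#' Full capacity panel for one sample
#'
#' Computes the five substrate-utilization capacities plus maximal ATP
#' production capacity and ATP/O2 under the fasted and postprandial
#' built-in profiles (and optionally an individualized panel), and the
#' whole-heart maximal ATP capacity when a heart mass is supplied.
#'
#' @param instance A `cardiocap_model` or `cardiocap_instance`.
#' @param heart_mass_mg Optional heart mass (mg) for whole-heart scaling.
#' @param panel Optional individualized plasma panel.
#' @param n_grid,max_fold Titration settings passed to [substrate_capacity()].
#' @return One-row data.frame with columns cap_glucose, cap_ffa,
#'   cap_lactate, cap_ketones, cap_bcaa, max_atp_fasted, max_atp_postprandial,
#'   atp_o2_fasted, atp_o2_postprandial, and optionally
#'   max_atp_individualized, atp_o2_individualized, whole_heart_max_atp.
#' @export
capacity_panel <- function(instance, heart_mass_mg = NULL, panel = NULL,
                           n_grid = 12, max_fold = 50) {
  fasted <- plasma_profile_builtin("fasted")
  caps <- vapply(c("glucose", "ffa", "lactate", "ketones", "bcaa"), function(s) {
    substrate_capacity(instance, s, base = fasted,
                       n_grid = n_grid, max_fold = max_fold)$capacity
  }, numeric(1))
  scan_f <- atp_load_scan(instance, fasted)
  scan_p <- atp_load_scan(instance, plasma_profile_builtin("postprandial"))
  out <- data.frame(
    cap_glucose = caps[["glucose"]], cap_ffa = caps[["ffa"]],
    cap_lactate = caps[["lactate"]], cap_ketones = caps[["ketones"]],
    cap_bcaa = caps[["bcaa"]],
    max_atp_fasted = scan_f$max_atp, atp_o2_fasted = scan_f$atp_o2_at_max,
    max_atp_postprandial = scan_p$max_atp, atp_o2_postprandial = scan_p$atp_o2_at_max)
  if (!is.null(panel)) {
    scan_i <- individualized_scan(instance, panel, defaults = fasted)
    out$max_atp_individualized <- scan_i$max_atp
    out$atp_o2_individualized <- scan_i$atp_o2_at_max
  }
  if (!is.null(heart_mass_mg))
    out$whole_heart_max_atp <- whole_heart_capacity(out$max_atp_fasted, heart_mass_mg)
  out
}

#' @export
print.cardiocap_load_scan <- function(x, ...) {
  cat("<load scan> profile=", x$profile, ", ", nrow(x$scan), " loads, plateau=",
      x$plateau, "\n  max ATP production ", signif(x$max_atp, 4),
      " mM/min, ATP/O2 ", signif(x$atp_o2_at_max, 4), "\n", sep = "")
  invisible(x)
}
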