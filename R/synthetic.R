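# Synthetic three-group cohort generator with planted ground truth.
#
# Emulates the statistical structure the analysis assumes: a control group,
# a diet-stressed group with down-regulated mitochondrial energy production
# (OXPHOS/TCA) and elevated inflammation, and a genetically obese group
# with up-regulated fatty-acid handling and collagens, down-regulated
# carbohydrate transport, shifted plasma panel (triglycerides and Leu/Ile
# up, ketones down), higher body and heart mass, and echo parameters
# coupled to the latent metabolic capacity.

.collagen_set <- c("Col1a1", "Col1a2", "Col3a1", "Col4a1", "Col5a1",
                   "Col5a2", "Col6a1", "Col6a2", "Col6a3", "Col15a1")
.inflammation_set <- c("B2m", "C3", "C1qa", "C1qb", "C1qc", "Cd68",
                       "Lgals3", "S100a8", "S100a9", "Anxa1", "Ptx3", "Lcn2")

#' Configuration of the synthetic cohort
#'
#' Defaults mirror the cohort structure the analysis is designed for:
#' groups of 4/5/5 animals, 2470 quantified proteins of which ~300 are
#' metabolic, log-normal intensity noise of 0.25 on the log2 scale, and
#' regulated fractions of the metabolic subset of 7.4% up / 34.6% down in
#' the diet group and 10.7% up / 22.8% down in the obese group.
#'
#' @param n_control,n_diet,n_obese Group sizes (each >= 3).
#' @param n_proteins,n_metabolic Total and metabolic protein counts.
#' @param noise_sd_log2 Log2-scale SD of the multiplicative intensity noise.
#' @param fold_down,fold_up Planted fold changes for regulated proteins.
#' @param frac_up,frac_down Named fractions (diet, obese) of the metabolic
#'   subset regulated up/down.
#' @param missing_rate Fraction of intensities set missing at random.
#' @param seed Integer seed fixing the whole cohort.
#' @return A `cardiocap_cohort_config` list.
#' @export
cohort_config <- function(n_control = 4, n_diet = 5, n_obese = 5,
                          n_proteins = 2470, n_metabolic = 300,
                          noise_sd_log2 = 0.25,
                          fold_down = 0.4, fold_up = 2.5,
                          frac_up = c(diet = 0.074, obese = 0.107),
                          frac_down = c(diet = 0.346, obese = 0.228),
                          missing_rate = 0, seed = 1L) {
  if (min(n_control, n_diet, n_obese) < 3) stop("each group needs n >= 3", call. = FALSE)
  if (fold_down <= 0 || fold_up <= 0) stop("fold changes must be > 0", call. = FALSE)
  if (n_metabolic > n_proteins) stop("n_metabolic > n_proteins", call. = FALSE)
  structure(list(n = c(control = n_control, diet = n_diet, obese = n_obese),
                 n_proteins = n_proteins, n_metabolic = n_metabolic,
                 noise_sd_log2 = noise_sd_log2,
                 fold_down = fold_down, fold_up = fold_up,
                 frac_up = frac_up, frac_down = frac_down,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cardiocap_cohort_config")
}

# protein universe: mapped enzymes + collagen/inflammation panels + filler
.protein_universe <- function(config, model) {
  mapped <- unique(unlist(lapply(model$reactions, function(r) r$proteins)))
  n_fill_met <- config$n_metabolic - length(mapped)
  if (n_fill_met < 0) stop("n_metabolic smaller than the mapped enzyme set", call. = FALSE)
  met_fill <- sprintf("Met%03d", seq_len(n_fill_met))
  metabolic <- c(mapped, met_fill)
  special <- c(.collagen_set, .inflammation_set)
  n_other <- config$n_proteins - config$n_metabolic - length(special)
  if (n_other < 0) stop("n_proteins too small for the protein panels", call. = FALSE)
  other <- sprintf("Prt%04d", seq_len(n_other))
  list(all = c(metabolic, special, other), metabolic = metabolic,
       mapped = mapped, collagen = .collagen_set,
       inflammation = .inflammation_set)
}

# group-level regulation plan: named fold-change vectors over proteins
.regulation_plan <- function(config, model, universe, null_cohort = FALSE) {
  plan <- list(diet = numeric(0), obese = numeric(0))
  if (null_cohort) return(plan)
  met <- universe$metabolic
  path_prot <- function(paths) unique(unlist(lapply(model$reactions, function(r)
    if (r$pathway %in% paths) r$proteins else NULL)))

  # fill beyond the targeted pathway cores from unmapped filler proteins
  # first, so planted pathway effects stay confined to their pathways
  filler_first <- function(pool) c(setdiff(pool, universe$mapped),
                                   intersect(pool, universe$mapped))
  mk <- function(core_down, core_up, frac_up, frac_down) {
    n_dn <- round(frac_down * length(met))
    n_up <- round(frac_up * length(met))
    dn <- core_down[seq_len(min(length(core_down), n_dn))]
    pool <- filler_first(setdiff(met, c(dn, core_up)))
    dn <- c(dn, pool[seq_len(max(0, n_dn - length(dn)))])
    up <- core_up[seq_len(min(length(core_up), n_up))]
    pool <- filler_first(setdiff(met, c(dn, up)))
    up <- c(up, pool[seq_len(max(0, n_up - length(up)))])
    c(setNames(rep(config$fold_down, length(dn)), dn),
      setNames(rep(config$fold_up, length(up)), up))
  }
  # diet group: mitochondrial energy production down, mild up-regulation
  plan$diet <- mk(core_down = path_prot(c("oxphos", "tca")),
                  core_up = character(),
                  config$frac_up[["diet"]], config$frac_down[["diet"]])
  # diet group: inflammation panel up (not part of the metabolic fractions)
  plan$diet <- c(plan$diet, setNames(rep(2.0, length(universe$inflammation)),
                                     universe$inflammation))
  # obese group: fatty-acid handling up, carbohydrate transport down,
  # collagens up
  plan$obese <- mk(core_down = path_prot(c("transport", "lactate-exchange", "glycolysis")),
                   core_up = path_prot("fao"),
                   config$frac_up[["obese"]], config$frac_down[["obese"]])
  plan$obese <- c(plan$obese, setNames(rep(2.5, length(universe$collagen)),
                                       universe$collagen))
  plan
}

#' Generate a synthetic three-group cohort
#'
#' Intensities are baseline x group fold change x log-normal noise; plasma
#' panels, body/heart masses and echocardiographic parameters follow
#' group-specific distributions; everything is reproducible from
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param model Reference model supplying the enzyme->reaction mapping
#'   (default: shipped model).
#' @param null_cohort Internal: drop all group effects (see
#'   [generate_null()]).
#' @return List with `matrix` (`cardiocap_abundance`), `metadata`
#'   (data.frame: sample, group, body_weight_g, heart_weight_mg, ef_pct,
#'   stroke_volume_ul, co_ml_min), `plasma` (per-sample panel incl. a
#'   triglycerides column the model deliberately has no substrate for), and
#'   `truth` (regulated proteins with fold changes per group, true
#'   per-reaction scales per group, causal markers per capacity, protein
#'   sets).
#' @export
generate_cohort <- function(config = cohort_config(), model = build_reference_model(),
                            null_cohort = FALSE) {
  stopifnot(inherits(config, "cardiocap_cohort_config"))
  set.seed(config$seed)
  uni <- .protein_universe(config, model)
  plan <- .regulation_plan(config, model, uni, null_cohort)

  groups <- rep(names(config$n), config$n)
  samples <- sprintf("%s_%02d", groups, unlist(lapply(config$n, seq_len)))
  names(groups) <- samples

  baseline <- setNames(stats::rlnorm(length(uni$all), meanlog = log(1e6), sdlog = 1),
                       uni$all)
  fc <- matrix(1, length(uni$all), length(samples),
               dimnames = list(uni$all, samples))
  for (g in names(plan)) {
    if (!length(plan[[g]])) next
    fc[names(plan[[g]]), groups == g] <- plan[[g]]
  }
  noise <- matrix(2^stats::rnorm(length(fc), 0, config$noise_sd_log2),
                  nrow(fc), ncol(fc))
  intensity <- baseline * fc * noise
  if (config$missing_rate > 0)
    intensity[stats::runif(length(intensity)) < config$missing_rate] <- NA
  matrix <- abundance_matrix(intensity, groups)

  # plasma panels (mM; insulin pM; tg is a non-substrate column by design)
  pm <- list(control = c(glucose = 5.8, fatty_acids = 0.5, lactate = 0.8,
                         valine = 0.2, leucine = 0.15, isoleucine = 0.06,
                         bhb = 0.08, acac = 0.04, tg = 1.0, insulin = 100),
             diet    = c(glucose = 5.8, fatty_acids = 0.55, lactate = 0.8,
                         valine = 0.2, leucine = 0.15, isoleucine = 0.06,
                         bhb = 0.08, acac = 0.04, tg = 1.0, insulin = 100),
             obese   = c(glucose = 6.5, fatty_acids = 0.55, lactate = 0.9,
                         valine = 0.3, leucine = 0.25, isoleucine = 0.11,
                         bhb = 0.04, acac = 0.02, tg = 2.2, insulin = 250))
  if (null_cohort) pm$diet <- pm$obese <- pm$control
  rel_sd <- 0.08
  plasma <- do.call(rbind, lapply(samples, function(s) {
    mu <- pm[[groups[[s]]]]
    v <- mu * pmax(1 + stats::rnorm(length(mu), 0, rel_sd), 0.05)
    as.data.frame(as.list(v))
  }))
  plasma <- cbind(sample = samples, plasma)

  # masses: heart mass down under diet stress, up with obesity
  mass_mu <- list(control = c(bw = 30, hw = 150), diet = c(bw = 31, hw = 132),
                  obese = c(bw = 48, hw = 205))
  if (null_cohort) mass_mu$diet <- mass_mu$obese <- mass_mu$control
  bw <- hw <- numeric(length(samples))
  for (i in seq_along(samples)) {
    mu <- mass_mu[[groups[[i]]]]
    bw[i] <- stats::rnorm(1, mu[["bw"]], 0.06 * mu[["bw"]])
    hw[i] <- stats::rnorm(1, mu[["hw"]], 0.06 * mu[["hw"]])
  }

  # true per-reaction vmax scales implied by the plan (geometric mean over
  # each reaction's protein set)
  scales <- sapply(names(config$n), function(g) {
    vapply(model$reactions, function(r) {
      if (!length(r$proteins)) return(1)
      f <- plan[[g]]
      vals <- ifelse(r$proteins %in% names(f), f[r$proteins], 1)
      exp(mean(log(vals)))
    }, numeric(1))
  })
  latent <- apply(scales[c("resp", "tca"), , drop = FALSE], 2,
                  function(x) exp(mean(log(x))))  # latent oxidative capacity
  fibrosis <- c(control = 0, diet = 0, obese = if (null_cohort) 0 else 1)

  ef <- 62 + 18 * (latent[groups] - 1) - 8 * fibrosis[groups] +
    stats::rnorm(length(samples), 0, 2)
  sv <- 32 + 10 * (latent[groups] - 1) + stats::rnorm(length(samples), 0, 2)
  hr <- stats::rnorm(length(samples), 480, 25)
  metadata <- data.frame(sample = samples, group = unname(groups),
                         body_weight_g = round(bw, 2),
                         heart_weight_mg = round(hw, 1),
                         ef_pct = round(unname(ef), 2),
                         stroke_volume_ul = round(unname(sv), 2),
                         co_ml_min = round(unname(sv * hr / 1000), 2),
                         stringsAsFactors = FALSE)

  truth <- list(
    regulated = lapply(plan, function(f)
      data.frame(protein = names(f), fold_change = unname(f),
                 stringsAsFactors = FALSE)),
    reaction_scales = scales,
    markers = list(
      cap_glucose = model$reactions$glut$proteins,
      cap_ffa = model$reactions$fao$proteins,
      cap_lactate = model$reactions$ldh$proteins,
      max_atp = unique(c(model$reactions$resp$proteins, model$reactions$tca$proteins))),
    protein_sets = list(metabolic = uni$metabolic, mapped = uni$mapped,
                        collagen = uni$collagen, inflammation = uni$inflammation))
  list(matrix = matrix, metadata = metadata, plasma = plasma, truth = truth)
}

#' Generate a null cohort (no group effects)
#'
#' Identical machinery to [generate_cohort()] with every fold change at 1
#' and identical plasma/mass/echo distributions across groups; the
#' calibration harness for type-I error suites.
#'
#' @inheritParams generate_cohort
#' @export
generate_null <- function(config = cohort_config(), model = build_reference_model()) {
  generate_cohort(config, model, null_cohort = TRUE)
}
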