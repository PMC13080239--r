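# Per-sample model instantiation: reaction Vmax values are scaled by the
# ratio of a sample's enzyme abundances to the control-group reference.

#' Control-group reference abundances
#'
#' Per-protein mean intensity over the control samples, ignoring missing
#' values. Proteins missing in every control sample get an NA reference and
#' are flagged; they are excluded from scaling downstream.
#'
#' @param matrix A `cardiocap_abundance` object (see [read_abundance()] /
#'   [abundance_matrix()]).
#' @param control_group Label of the control group.
#' @return Named numeric vector of reference intensities (NA where the
#'   protein was never observed in controls), with attribute `flagged`
#'   listing those protein IDs.
#' @export
reference_abundance <- function(matrix, control_group) {
  stopifnot(inherits(matrix, "cardiocap_abundance"))
  ctrl <- names(matrix$group)[matrix$group == control_group]
  if (length(ctrl) == 0) stop("control group '", control_group, "' is empty",
                              call. = FALSE)
  if (length(ctrl) < 2) stop("control group needs >= 2 samples", call. = FALSE)
  ref <- rowMeans(matrix$intensity[, ctrl, drop = FALSE], na.rm = TRUE)
  ref[is.nan(ref)] <- NA_real_
  flagged <- names(ref)[is.na(ref)]
  if (length(flagged))
    message(length(flagged), " protein(s) unobserved in all controls; excluded from scaling")
  attr(ref, "flagged") <- flagged
  ref
}

#' Read an enzyme-to-protein mapping table
#'
#' Two-column TSV (`reaction_id`, `protein_id`), one row per subunit. The
#' shipped mapping for the reduced reference network is loaded when `path`
#' is NULL.
#'
#' @param path TSV path, or NULL for the shipped mapping.
#' @param aggregation How multi-protein reactions aggregate subunit ratios:
#'   `"geometric-mean"` (default), `"minimum"`, or `"sum"`.
#' @return A `cardiocap_mapping`: list of protein-ID vectors per reaction
#'   plus the aggregation rule.
#' @export
read_mapping <- function(path = NULL, aggregation = c("geometric-mean", "minimum", "sum")) {
  aggregation <- match.arg(aggregation)
  if (is.null(path))
    path <- system.file("extdata", "mapping", "cardiac_reduced_v1_mapping.tsv",
                        package = "cardiocap", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "protein_id") %in% names(tab)))
    stop("mapping file needs columns reaction_id, protein_id", call. = FALSE)
  if (any(!grepl("^[A-Za-z0-9_.-]+$", tab$protein_id)))
    stop("malformed protein IDs in mapping", call. = FALSE)
  structure(list(map = split(tab$protein_id, tab$reaction_id),
                 aggregation = aggregation),
            class = "cardiocap_mapping")
}

#' Mapping derived from a model's own protein annotations
#' @param model A `cardiocap_model`.
#' @inheritParams read_mapping
#' @export
model_mapping <- function(model, aggregation = c("geometric-mean", "minimum", "sum")) {
  aggregation <- match.arg(aggregation)
  map <- lapply(model$reactions, function(r) r$proteins)
  map <- map[vapply(map, length, integer(1)) > 0]
  structure(list(map = map, aggregation = aggregation), class = "cardiocap_mapping")
}

.aggregate_abundance <- function(x, rule) {
  switch(rule,
         "geometric-mean" = exp(mean(log(x))),
         "minimum" = min(x),
         "sum" = sum(x))
}

#' Instantiate the model for one sample
#'
#' For every reaction with a protein mapping, the Vmax scaling factor is
#' `agg(sample intensities) / agg(reference intensities)` over the
#' reaction's protein set, using the mapping's aggregation rule (geometric
#' mean by default). Proteins without a usable reference are dropped from
#' the set; reactions whose proteins are all missing in the sample keep
#' scale 1 (conservative fallback) and are counted in `n_missing`. Scales
#' are clipped to [0.01, 100] with a warning.
#'
#' @param model A `cardiocap_model` (the reference model).
#' @param mapping A `cardiocap_mapping`.
#' @param matrix A `cardiocap_abundance`.
#' @param sample Sample ID present in the matrix.
#' @param reference Output of [reference_abundance()].
#' @param quiet Suppress per-reaction fallback messages.
#' @return A `cardiocap_instance`: list with `sample`, `model`, `scale`
#'   (named per-reaction factors; 1 for unmapped reactions), `n_missing`.
#' @export
instantiate <- function(model, mapping, matrix, sample, reference, quiet = FALSE) {
  stopifnot(inherits(model, "cardiocap_model"), inherits(mapping, "cardiocap_mapping"),
            inherits(matrix, "cardiocap_abundance"))
  if (!sample %in% matrix$samples)
    stop("unknown sample: ", sample, call. = FALSE)
  intens <- matrix$intensity[, sample]
  scale <- setNames(rep(1, length(model$reactions)), names(model$reactions))
  n_missing <- 0L
  for (rid in intersect(names(mapping$map), names(scale))) {
    prots <- mapping$map[[rid]]
    usable <- prots[prots %in% names(reference) & !is.na(reference[prots])]
    vals <- intens[usable]
    ok <- !is.na(vals)
    if (length(usable) == 0 || !any(ok)) {
      n_missing <- n_missing + 1L
      if (!quiet) message("sample ", sample, ": reaction ", rid,
                          " has no measured proteins; scale kept at 1")
      next
    }
    s <- .aggregate_abundance(vals[ok], mapping$aggregation) /
      .aggregate_abundance(reference[usable][ok], mapping$aggregation)
    if (s < 0.01 || s > 100) {
      warning("sample ", sample, ": scale ", signif(s, 3), " for ", rid,
              " clipped to [0.01, 100]", call. = FALSE)
      s <- min(max(s, 0.01), 100)
    }
    scale[rid] <- s
  }
  structure(list(sample = sample, model = model, scale = scale,
                 n_missing = n_missing),
            class = "cardiocap_instance")
}

#' Instantiate the whole cohort
#'
#' One [instantiate()] call per sample (control samples included; their
#' scales scatter around 1), in deterministic sample-ID order.
#'
#' @inheritParams instantiate
#' @param control_group Control group label used for the reference.
#' @return Named list of `cardiocap_instance` objects.
#' @export
instantiate_cohort <- function(model, mapping, matrix, control_group, quiet = TRUE) {
  reference <- reference_abundance(matrix, control_group)
  samples <- sort(matrix$samples)
  out <- lapply(samples, function(s)
    instantiate(model, mapping, matrix, s, reference, quiet = quiet))
  names(out) <- samples
  out
}

#' @export
print.cardiocap_instance <- function(x, ...) {
  mapped <- x$scale[x$scale != 1]
  cat("<sample instance> ", x$sample, ": ", length(mapped),
      " scaled reactions, ", x$n_missing, " fallback(s)\n", sep = "")
  if (length(mapped))
    cat("  ", paste(sprintf("%s=%.2f", names(mapped), mapped), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
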