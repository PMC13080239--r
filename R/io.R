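# File readers/writers and the pipeline driver. Canonical tabular format is
# TSV, UTF-8, '.' decimal, empty cell = missing.

#' Construct a protein abundance matrix container
#'
#' @param intensity Numeric matrix, proteins x samples; strictly positive
#'   where present, NA allowed.
#' @param group Named character vector mapping sample ID -> group label.
#' @return A `cardiocap_abundance` object.
#' @export
abundance_matrix <- function(intensity, group) {
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    stop("intensity matrix needs protein rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(intensity))) stop("duplicate protein IDs", call. = FALSE)
  if (anyDuplicated(colnames(intensity))) stop("duplicate sample IDs", call. = FALSE)
  if (any(intensity <= 0, na.rm = TRUE))
    stop("intensities must be strictly positive where present", call. = FALSE)
  group <- group[colnames(intensity)]
  if (anyNA(group)) stop("every sample needs a group label", call. = FALSE)
  structure(list(proteins = rownames(intensity), samples = colnames(intensity),
                 intensity = intensity, group = group),
            class = "cardiocap_abundance")
}

#' Read a protein abundance matrix from TSV
#'
#' First column = protein ID, remaining columns = samples. Non-positive
#' intensities and duplicate IDs are rejected; empty cells become NA.
#'
#' @param path TSV path.
#' @param metadata Metadata data.frame (from [read_metadata()]) supplying the
#'   sample -> group map; if NULL, all samples get group "unknown".
#' @return A `cardiocap_abundance`.
#' @export
read_abundance <- function(path, metadata = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("abundance table needs a protein column plus samples",
                          call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate protein ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ","), call. = FALSE)
  sn <- colnames(tab)[-1]
  if (anyDuplicated(sn))
    stop("duplicate sample column(s): ",
         paste(unique(sn[duplicated(sn)]), collapse = ","), call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(tab[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))) & !is.na(r) & r != "")))
    stop("malformed numeric value near line ", bad[1] + 1, call. = FALSE)
  }
  rownames(m) <- ids
  if (any(m <= 0, na.rm = TRUE)) {
    bad <- which(apply(m <= 0, 1, any, na.rm = TRUE))
    stop("non-positive intensity near line ", bad[1] + 1, call. = FALSE)
  }
  group <- if (is.null(metadata)) setNames(rep("unknown", length(sn)), sn)
           else setNames(metadata$group, metadata$sample)
  abundance_matrix(m, group)
}

#' Write a protein abundance matrix to TSV
#' @param matrix A `cardiocap_abundance`.
#' @param path Output path.
#' @export
write_abundance <- function(matrix, path) {
  df <- data.frame(protein_id = matrix$proteins, matrix$intensity,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Required columns: `sample`, `group`, `body_weight_g`, `heart_weight_mg`;
#' any additional numeric columns (echocardiographic parameters, plasma
#' panel fields) are kept.
#'
#' @param path TSV path.
#' @return data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "group", "body_weight_g", "heart_weight_mg")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ","),
                         call. = FALSE)
  if (anyDuplicated(tab$sample)) stop("duplicate sample IDs in metadata", call. = FALSE)
  tab
}

#' Write a data.frame as TSV (units in the column names where applicable)
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: instantiate (proteome scaling against the control group) ->
#' capacities (per-sample substrate capacities, fasted/postprandial load
#' scans, whole-heart scaling) -> stats (volcano vs control per group,
#' metabolic-subset PCA, correlation ledger over capacities and phenotypes).
#' All tables are written as TSV plus a JSON manifest (config echo, seed,
#' package version, input hashes) sufficient to reproduce every table.
#'
#' @param matrix A `cardiocap_abundance`.
#' @param metadata Metadata data.frame ([read_metadata()] layout).
#' @param model A `cardiocap_model`; default the shipped reference model.
#' @param mapping A `cardiocap_mapping`; default the shipped mapping.
#' @param control_group Control group label.
#' @param outdir Output directory (created if absent).
#' @param metabolic_proteins Optional character vector defining the
#'   metabolic protein subset for volcano fractions and PCA; defaults to
#'   all mapped proteins.
#' @param n_grid Titration grid size per substrate.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param stages Character subset of c("instantiate", "capacities", "stats").
#' @param capacities Cached capacity table (data.frame) allowing a
#'   stats-only rerun.
#' @return Invisible list with `capacities`, `stats`, `manifest`.
#' @export
run_pipeline <- function(matrix, metadata, model = build_reference_model(),
                         mapping = read_mapping(), control_group,
                         outdir, metabolic_proteins = NULL, n_grid = 8,
                         seed = 1L,
                         stages = c("instantiate", "capacities", "stats"),
                         capacities = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(metabolic_proteins))
    metabolic_proteins <- unique(unlist(mapping$map))

  caps <- capacities
  if ("capacities" %in% stages && is.null(caps)) {
    inst <- instantiate_cohort(model, mapping, matrix, control_group)
    caps <- do.call(rbind, lapply(names(inst), function(s) {
      hm <- metadata$heart_weight_mg[metadata$sample == s]
      cbind(sample = s,
            capacity_panel(inst[[s]], heart_mass_mg = hm, n_grid = n_grid))
    }))
    write_tsv(caps, file.path(outdir, "capacities.tsv"))
  }

  statlist <- NULL
  if ("stats" %in% stages) {
    groups <- setdiff(unique(matrix$group), control_group)
    volcano_tabs <- lapply(groups, function(g) {
      v <- volcano(matrix, control_group, g, subset = metabolic_proteins)
      write_tsv(v$table, file.path(outdir, paste0("volcano_", g, ".tsv")))
      v
    })
    names(volcano_tabs) <- groups
    pca_res <- pca(matrix, subset = metabolic_proteins)
    write_tsv(pca_res$scores, file.path(outdir, "pca_scores.tsv"))
    feats <- merge(caps, metadata, by = "sample")
    num <- feats[vapply(feats, is.numeric, logical(1))]
    rownames(num) <- feats$sample
    ledger <- correlation_ledger(num)
    write_tsv(data.frame(feature = rownames(ledger$signed), ledger$signed,
                         check.names = FALSE),
              file.path(outdir, "correlation_ledger_signed.tsv"))
    statlist <- list(volcano = volcano_tabs, pca = pca_res, ledger = ledger)
  }

  manifest <- list(
    schema_version = 1,
    package_version = as.character(utils::packageVersion("cardiocap")),
    seed = seed,
    control_group = control_group,
    model = model$name,
    stages = stages,
    n_samples = length(matrix$samples),
    n_proteins = length(matrix$proteins),
    config_hash = .hash_config(list(control_group, n_grid, stages)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(capacities = caps, stats = statlist, manifest = manifest))
}

.hash_config <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}
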