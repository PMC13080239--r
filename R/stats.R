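# The statistical layer: volcano classification, group tests with a
# normality gate, marker regression, pathway shares, correlation ledger,
# z-score clustering and PCA.

#' Volcano classification of protein abundance changes
#'
#' Fold change is mean(B)/mean(A) on the linear intensity scale; the
#' p-value comes from a two-sided Welch t-test on log2 intensities. A
#' protein is `down` iff FC < `fc_low` and p < `alpha`, `up` iff
#' FC > `fc_high` and p < `alpha`, otherwise `unchanged`. Summary fractions
#' are computed over `subset` only.
#'
#' @param matrix A `cardiocap_abundance`.
#' @param group_a,group_b Group labels (A = reference/control).
#' @param subset Protein IDs the summary fractions refer to; `NULL` = all.
#' @param fc_low,fc_high Linear fold-change thresholds (default 0.5 / 2).
#' @param alpha Significance threshold on the raw p-value.
#' @param adjust Apply Benjamini-Hochberg before thresholding (default off;
#'   fractions are conventionally reported on raw p).
#' @return A `cardiocap_volcano`: list with `table` (protein, log2_fc,
#'   p_value, class) and `summary` (n, frac_up, frac_down over the subset).
#' @export
volcano <- function(matrix, group_a, group_b, subset = NULL,
                    fc_low = 0.5, fc_high = 2, alpha = 0.05, adjust = FALSE) {
  stopifnot(inherits(matrix, "cardiocap_abundance"))
  a <- names(matrix$group)[matrix$group == group_a]
  b <- names(matrix$group)[matrix$group == group_b]
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 samples per group", call. = FALSE)
  A <- matrix$intensity[, a, drop = FALSE]
  B <- matrix$intensity[, b, drop = FALSE]
  fc <- rowMeans(B, na.rm = TRUE) / rowMeans(A, na.rm = TRUE)
  p <- vapply(seq_len(nrow(A)), function(i) {
    xa <- log2(A[i, ]); xb <- log2(B[i, ])
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    if (length(xa) < 2 || length(xb) < 2 ||
        (stats::sd(xa) == 0 && stats::sd(xb) == 0)) return(NA_real_)
    stats::t.test(xb, xa)$p.value
  }, numeric(1))
  p_thr <- if (adjust) stats::p.adjust(p, "BH") else p
  class <- rep("unchanged", length(fc))
  class[!is.na(p_thr) & p_thr < alpha & fc < fc_low] <- "down"
  class[!is.na(p_thr) & p_thr < alpha & fc > fc_high] <- "up"
  tab <- data.frame(protein = matrix$proteins, log2_fc = log2(fc),
                    p_value = p, class = class, stringsAsFactors = FALSE)
  if (is.null(subset)) subset <- matrix$proteins
  sel <- tab$protein %in% subset
  if (!any(sel)) warning("subset is disjoint from the matrix; empty summary",
                         call. = FALSE)
  n <- sum(sel)
  summ <- data.frame(n = n,
                     frac_up = if (n) mean(tab$class[sel] == "up") else NA_real_,
                     frac_down = if (n) mean(tab$class[sel] == "down") else NA_real_)
  structure(list(table = tab, summary = summ,
                 thresholds = c(fc_low = fc_low, fc_high = fc_high, alpha = alpha)),
            class = "cardiocap_volcano")
}

#' Two-group comparison with a Kolmogorov-Smirnov normality gate
#'
#' Each group is tested for normality with a one-sample KS test against a
#' normal with the group's mean and SD. If both groups pass at
#' `alpha_norm`, an unpaired two-sided Student t-test is used; otherwise
#' the two-sample Wilcoxon rank-sum test (the unpaired reading of a
#' signed-rank convention).
#'
#' @param values_a,values_b Numeric vectors, each n >= 3.
#' @param alpha Significance level reported alongside.
#' @param alpha_norm Normality-gate level.
#' @param var_equal Passed to [stats::t.test()] (classic Student test by
#'   default).
#' @return List with `statistic`, `p_value`, `test_used` ("t-test" or
#'   "rank-test"), `normality_p` (per group), `significant`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05, alpha_norm = 0.05,
                           var_equal = TRUE) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs n >= 3", call. = FALSE)
  ks_p <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(0)  # degenerate: fails the gate
    suppressWarnings(stats::ks.test(x, "pnorm", mean = mean(x), sd = s)$p.value)
  }
  np <- c(a = ks_p(values_a), b = ks_p(values_b))
  if (all(np > alpha_norm)) {
    tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                test_used = "t-test")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, exact = FALSE))
    res <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                test_used = "rank-test")
  }
  c(res, list(normality_p = np, significant = res$p_value < alpha))
}

#' Per-protein regression of a pathway capacity on protein abundance
#'
#' Ordinary least squares of the capacity on each pathway protein's
#' abundance across samples; slope, R-squared and p-value per protein, and
#' the count of significant markers at `alpha` (raw p by default).
#'
#' @param capacity Named per-sample capacity values.
#' @param matrix A `cardiocap_abundance` (samples must cover the capacity
#'   names).
#' @param pathway_proteins Protein IDs belonging to the pathway.
#' @param alpha Significance threshold.
#' @param adjust Benjamini-Hochberg toggle (default off).
#' @return A `cardiocap_marker_regression`: data.frame `table` (protein,
#'   slope, r_squared, p_value, significant) plus `n_significant`,
#'   `n_total`.
#' @export
marker_regression <- function(capacity, matrix, pathway_proteins, alpha = 0.05,
                              adjust = FALSE) {
  stopifnot(inherits(matrix, "cardiocap_abundance"))
  samples <- intersect(names(capacity), matrix$samples)
  if (length(samples) < 4) stop("need >= 4 samples with capacity and protein values",
                                call. = FALSE)
  prots <- intersect(pathway_proteins, matrix$proteins)
  rows <- lapply(prots, function(p) {
    x <- matrix$intensity[p, samples]
    y <- capacity[samples]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4) return(NULL)
    if (stats::sd(x[ok]) == 0) {
      message("protein ", p, " has constant abundance; skipped")
      return(NULL)
    }
    fit <- stats::lm(y[ok] ~ x[ok])
    sm <- summary(fit)
    data.frame(protein = p, slope = unname(stats::coef(fit)[2]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(protein = character(), slope = numeric(),
                                      r_squared = numeric(), p_value = numeric())
  p_thr <- if (adjust) stats::p.adjust(tab$p_value, "BH") else tab$p_value
  tab$significant <- p_thr < alpha
  structure(list(table = tab, n_significant = sum(tab$significant),
                 n_total = nrow(tab)),
            class = "cardiocap_marker_regression")
}

#' Per-sample pathway share of total protein intensity
#'
#' Share = sum of intensities over the protein set / sum over all proteins,
#' per sample (used for collagen and inflammation scores). Also returns the
#' per-protein z-scored means per group for heatmap-style export.
#'
#' @param matrix A `cardiocap_abundance`.
#' @param protein_set Protein IDs; must intersect the matrix.
#' @return List with `share` (named per-sample), `zscores` (protein x group
#'   matrix of z-scored group means).
#' @export
pathway_score <- function(matrix, protein_set) {
  stopifnot(inherits(matrix, "cardiocap_abundance"))
  sel <- matrix$proteins %in% protein_set
  if (!any(sel)) stop("protein set does not intersect the matrix", call. = FALSE)
  tot <- colSums(matrix$intensity, na.rm = TRUE)
  share <- colSums(matrix$intensity[sel, , drop = FALSE], na.rm = TRUE) / tot
  groups <- unique(matrix$group)
  gm <- sapply(groups, function(g)
    rowMeans(matrix$intensity[sel, matrix$group == g, drop = FALSE], na.rm = TRUE))
  z <- t(apply(gm, 1, function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0))
  colnames(z) <- groups
  list(share = share, zscores = z)
}

#' Regression of a pathway score on each capacity readout
#'
#' [marker_regression()] with the roles swapped: the score (e.g.
#' inflammation share) is regressed on each column of a per-sample capacity
#' panel; R-squared, slope and p per capacity.
#'
#' @param score Named per-sample score.
#' @param capacities data.frame of per-sample capacity readouts with a
#'   `sample` column (as from [run_pipeline()]) or named rows.
#' @param alpha Significance threshold.
#' @return data.frame: capacity, slope, r_squared, p_value, significant.
#' @export
score_capacity_regression <- function(score, capacities, alpha = 0.05) {
  if ("sample" %in% names(capacities)) {
    rownames(capacities) <- capacities$sample
    capacities <- capacities[setdiff(names(capacities), "sample")]
  }
  samples <- intersect(names(score), rownames(capacities))
  if (length(samples) < 4) stop("need >= 4 samples", call. = FALSE)
  num <- capacities[samples, vapply(capacities, is.numeric, logical(1)), drop = FALSE]
  rows <- lapply(names(num), function(cn) {
    x <- num[[cn]]
    if (stats::sd(x) == 0) return(NULL)
    fit <- stats::lm(score[samples] ~ x)
    sm <- summary(fit)
    data.frame(capacity = cn, slope = unname(stats::coef(fit)[2]),
               r_squared = sm$r.squared, p_value = sm$coefficients[2, 4],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$significant <- tab$p_value < alpha
  tab
}

#' Pairwise Pearson correlation ledger with significance mask
#'
#' Pearson r and two-sided p for every feature pair (pairwise-complete
#' observations), the significance mask at `alpha`, and the signed
#' significance matrix (-1/0/+1). Zero-variance features are excluded with
#' a note.
#'
#' @param features Numeric data.frame or matrix, samples x features.
#' @param alpha Significance level of the mask.
#' @param provenance Optional named character vector tagging features as
#'   "model-derived" or "measured".
#' @return A `cardiocap_ledger`: list with `r`, `p`, `n` (pairwise sample
#'   counts), `mask` (logical), `signed` (-1/0/+1), `provenance`.
#' @export
correlation_ledger <- function(features, alpha = 0.05, provenance = NULL) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("features must be numeric", call. = FALSE)
  if (nrow(X) < 4) stop("need >= 4 samples", call. = FALSE)
  keep <- apply(X, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
  if (any(!keep))
    message("excluded zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  k <- ncol(X)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(k)) {
    r[i, i] <- 1; p[i, i] <- 0; n[i, i] <- sum(is.finite(X[, i]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- is.finite(X[, i]) & is.finite(X[, j])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 4) next
      ct <- suppressWarnings(stats::cor.test(X[ok, i], X[ok, j]))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  mask <- !is.na(p) & p < alpha
  diag(mask) <- FALSE
  signed <- sign(r) * mask
  structure(list(r = r, p = p, n = n, mask = mask, signed = signed,
                 alpha = alpha, provenance = provenance),
            class = "cardiocap_ledger")
}

#' Z-score a feature matrix (features in rows)
#'
#' Per-row transform to mean 0, sd 1; constant rows are dropped with a
#' note.
#'
#' @param x Numeric matrix, features x samples.
#' @return Z-scored matrix (possibly fewer rows).
#' @export
zscore <- function(x) {
  sds <- apply(x, 1, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    message("dropped constant feature(s): ",
            paste(rownames(x)[sds == 0], collapse = ", "))
  x <- x[is.finite(sds) & sds > 0, , drop = FALSE]
  t(scale(t(x)))
}

#' Hierarchical clustering of z-scored features and samples
#'
#' Average-linkage agglomerative clustering on Euclidean distances of
#' z-scored values (rows = features, columns = samples), deterministic
#' input-order tie-break; returns the dendrograms and leaf orderings.
#'
#' @param matrix A `cardiocap_abundance` or a plain numeric matrix
#'   (features x samples).
#' @param subset Optional feature subset (row IDs).
#' @return List with `row_order`, `col_order`, `row_hclust`, `col_hclust`,
#'   `z` (the z-scored matrix).
#' @export
zscore_cluster <- function(matrix, subset = NULL) {
  x <- if (inherits(matrix, "cardiocap_abundance")) matrix$intensity else as.matrix(matrix)
  if (!is.null(subset)) x <- x[rownames(x) %in% subset, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 rows and columns", call. = FALSE)
  z <- zscore(x)
  hr <- stats::hclust(stats::dist(z), method = "average")
  hc <- stats::hclust(stats::dist(t(z)), method = "average")
  list(row_order = rownames(z)[hr$order], col_order = colnames(z)[hc$order],
       row_hclust = hr, col_hclust = hc, z = z)
}

#' PCA of z-scored features with a deterministic sign convention
#'
#' Principal component analysis of samples over z-scored features; each
#' component's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param matrix A `cardiocap_abundance` or numeric matrix (features x
#'   samples).
#' @param subset Optional feature subset.
#' @return List with `scores` (data.frame sample, group if known, PC
#'   columns), `explained` (variance fractions), `loadings`.
#' @export
pca <- function(matrix, subset = NULL) {
  group <- NULL
  x <- if (inherits(matrix, "cardiocap_abundance")) {
    group <- matrix$group
    matrix$intensity
  } else as.matrix(matrix)
  if (!is.null(subset)) x <- x[rownames(x) %in% subset, , drop = FALSE]
  z <- zscore(x)
  z <- z[stats::complete.cases(z), , drop = FALSE]
  pr <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- data.frame(sample = rownames(pr$x), pr$x, check.names = FALSE,
                       stringsAsFactors = FALSE)
  if (!is.null(group)) scores$group <- group[scores$sample]
  list(scores = scores, explained = expl, loadings = pr$rotation)
}
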