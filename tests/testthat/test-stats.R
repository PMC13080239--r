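test_that("volcano classification follows the fold-change/p thresholds exactly", {
  # constructed cases: tight FC 0.4 -> down; noisy FC 2.5 -> unchanged
  intens <- rbind(
    Pdown = c(100, 101, 99, 100, 40, 40.2, 39.8, 40),
    Pnoisy = c(100, 101, 99, 100, 50, 100, 220, 630),
    Pflat = c(100, 101, 99, 100, 100, 101, 99, 100))
  colnames(intens) <- paste0("s", 1:8)
  g <- setNames(rep(c("A", "B"), each = 4), colnames(intens))
  v <- volcano(abundance_matrix(intens, g), "A", "B")
  cls <- setNames(v$table$class, v$table$protein)
  fc <- setNames(2^v$table$log2_fc, v$table$protein)
  expect_lt(fc[["Pdown"]], 0.5); expect_lt(v$table$p_value[1], 0.05)
  expect_identical(cls[["Pdown"]], "down")
  expect_gt(fc[["Pnoisy"]], 2); expect_gt(v$table$p_value[2], 0.05)
  expect_identical(cls[["Pnoisy"]], "unchanged")
  expect_identical(cls[["Pflat"]], "unchanged")

  # identical groups: nothing regulated
  same <- intens[, c(1:4, 1:4)]
  colnames(same) <- paste0("s", 1:8)
  v0 <- volcano(abundance_matrix(same, g), "A", "B")
  expect_equal(v0$summary$frac_up, 0)
  expect_equal(v0$summary$frac_down, 0)

  expect_warning(volcano(abundance_matrix(intens, g), "A", "B",
                         subset = "NotThere"), "disjoint")
})

test_that("group comparison gates on KS normality and matches the closed-form t", {
  a <- c(4.8, 5.2, 5.0, 5.4, 4.9, 5.1)
  b <- c(5.6, 6.0, 5.8, 6.2, 5.7, 6.1)
  res <- compare_groups(a, b)
  expect_identical(res$test_used, "t-test")
  # hand-computed pooled-variance t statistic
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_true(res$significant)

  # identical groups: no difference
  res0 <- compare_groups(a, a)
  expect_equal(res0$p_value, 1, tolerance = 1e-9)

  # grossly non-normal values fall back to the rank test
  skew <- c(rep(c(1, 1.1, 1.2), 6), 300, 400, 500)
  res_r <- compare_groups(skew, skew + 0.1)
  expect_identical(res_r$test_used, "rank-test")

  expect_error(compare_groups(c(1, 2), b), "n >= 3")
})

test_that("group-comparison type-I error sits at the nominal level", {
  set.seed(402)
  rej <- vapply(seq_len(2000), function(i) {
    compare_groups(rnorm(8), rnorm(8))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("marker regression recovers exact and absent linear relations", {
  intens <- rbind(Px = c(1, 2, 3, 4, 5) * 10,
                  Pz = c(5, 3, 4, 1, 2) * 10)
  colnames(intens) <- paste0("s", 1:5)
  g <- setNames(rep("g", 5), colnames(intens))
  mat <- abundance_matrix(intens, g)
  capacity <- setNames(3 + 0.2 * intens["Px", ], colnames(intens))
  mr <- suppressWarnings(marker_regression(capacity, mat, c("Px", "Pz")))
  tab <- mr$table
  expect_equal(tab$r_squared[tab$protein == "Px"], 1, tolerance = 1e-12)
  expect_equal(tab$slope[tab$protein == "Px"], 0.2, tolerance = 1e-12)
  expect_lt(tab$p_value[tab$protein == "Px"], 1e-6)
  # 5-point hand OLS for the unrelated protein
  x <- intens["Pz", ]; y <- capacity
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(tab$slope[tab$protein == "Pz"], unname(slope_hand), tolerance = 1e-12)
  expect_equal(mr$n_total, 2L)

  # constant-abundance proteins are skipped with a note
  intens2 <- rbind(intens, Pc = rep(7, 5))
  colnames(intens2) <- colnames(intens)
  expect_message(mr2 <- suppressWarnings(
    marker_regression(capacity, abundance_matrix(intens2, g),
                      c("Px", "Pz", "Pc"))), "constant")
  expect_equal(mr2$n_total, 2L)
})

test_that("marker regression attains the planted sensitivity/FPR operating point", {
  # planted markers: capacity = protein + noise at SD ratio 1.5, n = 10
  sens <- fpr <- numeric(50)
  set.seed(77)
  for (k in 1:50) {
    n <- 10
    latent <- rnorm(n)
    causal <- t(vapply(1:10, function(i) latent + rnorm(n, 0, 1 / 1.5), numeric(n)))
    nullp <- t(vapply(1:40, function(i) rnorm(n), numeric(n)))
    intens <- 1000 + 150 * rbind(causal, nullp)
    rownames(intens) <- c(sprintf("C%02d", 1:10), sprintf("N%02d", 1:40))
    colnames(intens) <- sprintf("s%02d", 1:n)
    mat <- abundance_matrix(intens, setNames(rep("g", n), colnames(intens)))
    capacity <- setNames(latent, colnames(intens))
    # regress on log-scale abundance structure via the intensities directly
    mr <- marker_regression(capacity, mat, rownames(intens))
    sig <- setNames(mr$table$significant, mr$table$protein)
    sens[k] <- mean(sig[grep("^C", names(sig))])
    fpr[k] <- mean(sig[grep("^N", names(sig))])
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fpr), 0.2)
})

test_that("pathway scores are intensity shares with the expected arithmetic", {
  intens <- rbind(A = c(2, 4), B = c(3, 1), C = c(5, 5))
  colnames(intens) <- c("s1", "s2")
  mat <- abundance_matrix(intens, c(s1 = "g1", s2 = "g2"))
  ps <- pathway_score(mat, c("A", "B"))
  expect_equal(unname(ps$share), c((2 + 3) / 10, (4 + 1) / 10))
  expect_equal(unname(pathway_score(mat, c("A", "B", "C"))$share), c(1, 1))
  expect_error(pathway_score(mat, "ghost"), "does not intersect")

  # doubling all set members in one sample raises that sample's share
  intens2 <- intens; intens2[c("A", "B"), "s2"] <- intens2[c("A", "B"), "s2"] * 2
  ps2 <- pathway_score(abundance_matrix(intens2, c(s1 = "g1", s2 = "g2")), c("A", "B"))
  expect_gt(ps2$share[["s2"]], ps$share[["s2"]])
})

test_that("score-capacity regression detects exact couplings and stays calibrated", {
  caps <- data.frame(sample = sprintf("s%d", 1:8),
                     max_atp = c(30, 34, 28, 40, 25, 37, 31, 29))
  score <- setNames(0.1 - 0.002 * caps$max_atp, caps$sample)
  tab <- suppressWarnings(score_capacity_regression(score, caps))
  expect_equal(tab$r_squared[tab$capacity == "max_atp"], 1, tolerance = 1e-12)
  expect_lt(tab$slope[tab$capacity == "max_atp"], 0)

  set.seed(12)
  sig <- vapply(seq_len(2000), function(i) {
    s <- setNames(rnorm(8), caps$sample)
    score_capacity_regression(s, caps)$p_value[1] < 0.05
  }, logical(1))
  expect_lt(abs(mean(sig) - 0.05), 0.02)
})

test_that("the correlation ledger is symmetric, masked, and calibrated", {
  X <- data.frame(a = c(1, 2, 3, 4, 6), b = c(2, 4.1, 5.9, 8, 12.2),
                  c = c(5, 1, 4, 2, 3))
  led <- correlation_ledger(X)
  expect_equal(diag(led$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(led$r, t(led$r))
  expect_equal(led$mask, t(led$mask))
  # 4+ point hand-computed Pearson r
  r_hand <- cov(X$a, X$b) / (sd(X$a) * sd(X$b))
  expect_equal(led$r["a", "b"], r_hand, tolerance = 1e-12)
  expect_true(led$signed["a", "b"] %in% c(0, 1))
  expect_true(all(led$signed %in% c(-1, 0, 1)))

  expect_message(correlation_ledger(cbind(X, flat = rep(1, 5))), "zero-variance")

  set.seed(9)
  sig <- vapply(seq_len(2000), function(i) {
    Y <- data.frame(u = rnorm(10), v = rnorm(10))
    correlation_ledger(Y)$mask["u", "v"]
  }, logical(1))
  expect_lt(abs(mean(sig) - 0.05), 0.02)
})

test_that("z-scoring, clustering and PCA behave deterministically", {
  m <- matrix(rnorm(60, 10, 3), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  z <- zscore(m)
  expect_equal(unname(rowMeans(z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 6), tolerance = 1e-12)

  # duplicated samples merge first (distance zero)
  m2 <- m; m2[, "s2"] <- m2[, "s1"]
  cl <- zscore_cluster(m2)
  h <- cl$col_hclust
  first <- sort(colnames(m2)[-h$merge[1, ]])
  expect_equal(first, c("s1", "s2"))
  expect_equal(h$height[1], 0, tolerance = 1e-12)

  # PCA sign convention makes repeated runs identical
  p1 <- pca(m); p2 <- pca(m)
  expect_identical(p1$scores, p2$scores)
  expect_equal(sum(p1$explained), 1, tolerance = 1e-12)

  # constant features are dropped with a note
  m3 <- rbind(m, const = rep(5, 10))
  expect_message(zscore(m3), "constant")
})

test_that("three-group cohorts separate along PC1 of the metabolic subset", {
  coh <- generate_cohort(small_config(seed = 21))
  p <- pca(coh$matrix, subset = coh$truth$protein_sets$metabolic)
  s <- silhouette1d(p$scores$PC1, p$scores$group)
  expect_gt(mean(s), 0)
})
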