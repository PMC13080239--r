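ref <- build_reference_model()

test_that("reference abundance is the control-group mean with flagging", {
  m <- toy_matrix()
  r <- reference_abundance(m, "ctrl")
  expect_equal(unname(r["P1"]), 15)
  expect_equal(unname(r["P2"]), 5)
  expect_error(reference_abundance(m, "nothere"), "empty")

  # a protein unobserved in all controls is flagged and excluded
  mm <- m
  mm$intensity["P3", c("c1", "c2")] <- NA
  expect_message(r2 <- reference_abundance(mm, "ctrl"), "unobserved")
  expect_true("P3" %in% attr(r2, "flagged"))
  expect_true(is.na(r2["P3"]))
})

test_that("instantiation scales follow the abundance ratios", {
  m <- build_chain()
  mapping <- model_mapping(m)
  intens <- rbind(TrpA = c(10, 10, 20, 5), EnzB = c(4, 4, 16, 4))
  colnames(intens) <- c("c1", "c2", "s1", "s2")
  mat <- abundance_matrix(intens,
    c(c1 = "ctrl", c2 = "ctrl", s1 = "trt", s2 = "trt"))
  r <- reference_abundance(mat, "ctrl")

  # identity: the reference profile itself gives scale exactly 1
  id <- instantiate(m, mapping, mat, "c1", r, quiet = TRUE)
  expect_equal(unname(id$scale[c("upt", "conv")]), c(1, 1))

  # single-protein reaction at 2x reference -> scale 2; 4x -> 4
  s1 <- instantiate(m, mapping, mat, "s1", r, quiet = TRUE)
  expect_equal(unname(s1$scale["upt"]), 2)
  expect_equal(unname(s1$scale["conv"]), 4)
  expect_equal(unname(s1$scale["atp_demand"]), 1)  # unmapped stays 1

  expect_error(instantiate(m, mapping, mat, "ghost", r), "unknown sample")
})

test_that("two-subunit reactions aggregate by geometric mean", {
  def <- chain_def()
  def$reactions[[2]]$proteins <- list("EnzB", "EnzB2")
  m <- build_model(def)
  mapping <- model_mapping(m)
  intens <- rbind(TrpA = c(10, 10, 10), EnzB = c(4, 4, 16), EnzB2 = c(8, 8, 8))
  colnames(intens) <- c("c1", "c2", "s1")
  mat <- abundance_matrix(intens, c(c1 = "ctrl", c2 = "ctrl", s1 = "trt"))
  r <- reference_abundance(mat, "ctrl")
  s1 <- instantiate(m, mapping, mat, "s1", r, quiet = TRUE)
  expect_equal(unname(s1$scale["conv"]), sqrt(4 * 1))  # sqrt(4x * 1x) = 2

  # monotonicity: raising one subunit never lowers the scale
  mat2 <- mat
  mat2$intensity["EnzB2", "s1"] <- 12
  s1b <- instantiate(m, mapping, mat2, "s1", r, quiet = TRUE)
  expect_gte(s1b$scale[["conv"]], s1$scale[["conv"]])

  # alternative aggregation: ratio of aggregates, min(16,8)/min(4,8)
  map_min <- model_mapping(m, aggregation = "minimum")
  expect_equal(unname(instantiate(m, map_min, mat, "s1", r, quiet = TRUE)$scale["conv"]),
               min(16, 8) / min(4, 8))
})

test_that("missing proteins fall back to scale 1 and are counted", {
  m <- build_chain()
  mapping <- model_mapping(m)
  intens <- rbind(TrpA = c(10, 10, NA), EnzB = c(4, 4, 8))
  colnames(intens) <- c("c1", "c2", "s1")
  mat <- abundance_matrix(intens, c(c1 = "ctrl", c2 = "ctrl", s1 = "trt"))
  r <- reference_abundance(mat, "ctrl")
  expect_message(s1 <- instantiate(m, mapping, mat, "s1", r, quiet = FALSE),
                 "no measured proteins")
  expect_equal(unname(s1$scale["upt"]), 1)
  expect_equal(s1$n_missing, 1L)
})

test_that("extreme ratios are clipped with a warning", {
  m <- build_chain()
  mapping <- model_mapping(m)
  intens <- rbind(TrpA = c(10, 10, 10000), EnzB = c(4, 4, 4))
  colnames(intens) <- c("c1", "c2", "s1")
  mat <- abundance_matrix(intens, c(c1 = "ctrl", c2 = "ctrl", s1 = "trt"))
  r <- reference_abundance(mat, "ctrl")
  expect_warning(s1 <- instantiate(m, mapping, mat, "s1", r, quiet = TRUE), "clipped")
  expect_equal(unname(s1$scale["upt"]), 100)
})

test_that("cohort instantiation is complete, ordered, and robust to missingness", {
  cfg <- small_config(missing_rate = 0.1, seed = 11)
  coh <- generate_cohort(cfg, ref)
  inst <- instantiate_cohort(ref, read_mapping(), coh$matrix, "control")
  expect_length(inst, 14)
  expect_equal(names(inst), sort(coh$matrix$samples))
  expect_true(all(vapply(inst, function(i) all(i$scale > 0), logical(1))))

  # planted OXPHOS/TCA down-regulation is recovered in the diet-group scales
  diet_resp <- vapply(inst[grep("diet", names(inst))], function(i) i$scale[["resp"]],
                      numeric(1))
  ctrl_resp <- vapply(inst[grep("control", names(inst))], function(i) i$scale[["resp"]],
                      numeric(1))
  expect_equal(mean(diet_resp), cfg$fold_down, tolerance = 0.15)
  expect_equal(mean(ctrl_resp), 1, tolerance = 0.15)
})

test_that("halving OXPHOS protein abundance halves maximal ATP capacity", {
  mapping <- read_mapping()
  oxphos <- mapping$map[["resp"]]
  col <- matrix(1000, length(oxphos), 1, dimnames = list(oxphos, NULL))
  mat <- cbind(col, col, col * 0.5)
  colnames(mat) <- c("c1", "c2", "s1")
  mat <- abundance_matrix(mat, c(c1 = "ctrl", c2 = "ctrl", s1 = "half"))
  r <- reference_abundance(mat, "ctrl")
  half <- instantiate(ref, mapping, mat, "s1", r, quiet = TRUE)
  expect_equal(unname(half$scale["resp"]), 0.5)
  fasted <- plasma_profile_builtin("fasted")
  full_cap <- atp_load_scan(ref, fasted)$max_atp
  half_cap <- atp_load_scan(half, fasted)$max_atp
  expect_equal(half_cap / full_cap, 0.5, tolerance = 0.05)
})
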