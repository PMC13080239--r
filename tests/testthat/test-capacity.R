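ref <- build_reference_model()
fasted <- plasma_profile_builtin("fasted")
postprandial <- plasma_profile_builtin("postprandial")

test_that("built-in plasma profiles carry the physiological state values", {
  expect_equal(unlist(fasted[c("glucose", "fatty_acids", "lactate", "valine",
                               "leucine", "isoleucine", "bhb", "acac")]),
               c(glucose = 5.8, fatty_acids = 0.5, lactate = 0.8, valine = 0.2,
                 leucine = 0.15, isoleucine = 0.06, bhb = 0.08, acac = 0.04))
  expect_equal(fasted$insulin, 100)
  expect_equal(postprandial$insulin, 600)
  expect_equal(postprandial$glucose, 7.8)
  expect_equal(postprandial$bhb, 0)
  expect_equal(fasted$catecholamines, 0.75)
  expect_error(plasma_profile(glucose = -1, fatty_acids = 0, lactate = 0,
                              valine = 0, leucine = 0, isoleucine = 0,
                              bhb = 0, acac = 0, insulin = 0), ">= 0")
})

test_that("load ramp is monotone, normalized, and bounded by the stoichiometric ATP/O2", {
  sc <- atp_load_scan(ref, fasted)
  expect_true(sc$plateau)
  expect_true(all(diff(sc$scan$atp_production) >= -1e-6))
  shares <- rowSums(sc$scan[grep("^share_", names(sc$scan))])
  expect_true(all(abs(shares - 1) < 1e-6))
  expect_true(all(sc$scan$atp_o2 <= ref$atp_o2_max + 1e-9))
  expect_gt(sc$atp_o2_at_max, 0)
  expect_equal(sc$scan$atp_production[1],
               with(sc$scan, load[1]) * 0.94, tolerance = 0.07)  # vATP ~ load at high ATP
})

test_that("substrate contributions attribute fluxes by stoichiometric yield", {
  ss <- solve_steady_state(ref, fasted, load = 20)
  contrib <- substrate_contributions(ss, ref)
  expect_equal(sum(contrib), ss$atp_production, tolerance = 1e-6 * ss$atp_production)
  # hand check: ffa contribution = uptake flux x computed yield
  expect_equal(unname(contrib["ffa"]),
               unname(ss$flux["fao"] * ref$atp_yield["ffa_e"]), tolerance = 1e-10)
  # no ketones in the postprandial profile -> zero ketone contribution
  ssp <- solve_steady_state(ref, postprandial, load = 20)
  expect_equal(unname(substrate_contributions(ssp, ref)["ketones"]), 0,
               tolerance = 1e-10)
})

test_that("single-transporter uptake capacity saturates at the transporter vmax", {
  m <- build_chain(s_conc = 1, vup = 2, km = 0.05, vconv = 100, load_rest = 10)
  cap <- substrate_capacity(m, "fuel", base = fasted, n_grid = 10, demand_fold = 10)
  expect_equal(cap$capacity, 2, tolerance = 0.01)  # -> vmax as S >> Km
  expect_true(cap$plateau)
  # clamping the substrate to zero gives zero capacity
  cap0 <- substrate_capacity(m, "fuel", base = fasted, grid = c(0, 0, 0))
  expect_equal(cap0$capacity, 0, tolerance = 1e-9)
})

test_that("titrating the reference model yields positive, scale-proportional capacities", {
  glc <- substrate_capacity(ref, "glucose", n_grid = 8)
  expect_gt(glc$capacity, 0)
  # halved glycolytic machinery halves the uptake-limited glucose capacity
  rids <- names(ref$reactions)
  inst <- structure(list(model = ref, scale = setNames(rep(1, length(rids)), rids)),
                    class = "cardiocap_instance")
  inst$scale[c("glut", "glyc")] <- 0.5
  glc_half <- substrate_capacity(inst, "glucose", n_grid = 8)
  expect_equal(glc_half$capacity / glc$capacity, 0.5, tolerance = 0.05)
})

test_that("capacity scales homogeneously with a global enzyme factor", {
  rids <- setdiff(names(ref$reactions), ref$demand_id)
  base <- substrate_capacity(ref, "ffa", n_grid = 6)
  alpha <- 1.5
  inst <- structure(list(model = ref, scale = setNames(rep(alpha, length(rids)), rids)),
                    class = "cardiocap_instance")
  # demand ancillary load also scales with alpha through demand_fold x load_rest:
  scaled <- substrate_capacity(inst, "ffa", n_grid = 6, demand_fold = 10 * alpha)
  expect_equal(scaled$capacity / base$capacity, alpha, tolerance = 1e-3)
})

test_that("whole-heart scaling is plain arithmetic with unit conversion", {
  expect_equal(whole_heart_capacity(10, 200), 2)
  expect_equal(whole_heart_capacity(0, 150), 0)
  expect_error(whole_heart_capacity(10, 0), "> 0")
  # same per-gram capacity, 1.4x heart mass -> 1.4x whole-heart capacity
  expect_equal(whole_heart_capacity(10, 1.4 * 150) / whole_heart_capacity(10, 150), 1.4)
})

test_that("individualized scans merge panels field-by-field", {
  # a panel identical to the defaults reproduces the default scan exactly
  panel <- unlist(fasted[c("glucose", "fatty_acids", "bhb")])
  names(panel) <- c("glucose", "fatty_acids", "bhb")
  sc_def <- atp_load_scan(ref, fasted)
  sc_ind <- suppressMessages(individualized_scan(ref, panel, defaults = fasted))
  expect_equal(sc_ind$max_atp, sc_def$max_atp, tolerance = 1e-12)
  expect_equal(sc_ind$scan$atp_production, sc_def$scan$atp_production, tolerance = 1e-12)

  # doubling only bhb barely moves the capacity (ketone share is small)
  sc_bhb <- suppressMessages(individualized_scan(ref, c(bhb = 2 * fasted$bhb),
                                                 defaults = fasted))
  expect_lt(abs(sc_bhb$max_atp - sc_def$max_atp) / sc_def$max_atp, 0.02)

  # non-substrate fields (triglycerides) are dropped with a message
  expect_message(merge_plasma_panel(c(tg = 2.0), fasted), "not a model substrate")
  expect_warning(merge_plasma_panel(list(), fasted), "empty")
  expect_error(merge_plasma_panel(c(glucose = -2), fasted), "finite and >= 0")
})
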