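test_that("screen generation is deterministic under a fixed seed", {
  a <- small_screen(seed = 7)
  b <- small_screen(seed = 7)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c <- small_screen(seed = 8)
  expect_false(identical(a$observations$gfp, c$observations$gfp))
})

test_that("plate geometry is conserved: full grids, quadruplicate blocks", {
  sim <- small_screen(seed = 3, n_plates = 2)
  obs <- sim$observations
  per_plate <- table(obs$reporter, obs$plate_id)
  expect_true(all(per_plate == 32 * 48))
  colonies <- table(obs$strain_id[obs$reporter == "NMD"])
  expect_true(all(colonies == 4))
  # each strain's four positions sit on one plate, in a 2x2 block
  one <- obs[obs$reporter == "NMD" & obs$strain_id == sim$truth$strain_id[
    which(!sim$truth$is_border)[1]], ]
  expect_equal(length(unique(one$plate_id)), 1)
  expect_equal(diff(range(one$row)), 1)
  expect_equal(diff(range(one$col)), 1)
  # border flag marks exactly the outermost ring of spots
  nmd <- obs[obs$reporter == "NMD", ]
  on_edge <- nmd$row %in% c(1, 2, 31, 32) | nmd$col %in% c(1, 2, 47, 48)
  expect_identical(nmd$is_border, on_edge)
})

test_that("null config gives baseline log-ratios; planted fractions are honoured", {
  sim <- generate_screen(screen_sim_config(
    n_plates = 1, frac_nmd_hits = 0, frac_opt_hits = 0, frac_shared_hits = 0,
    spatial_amplitude = 0, noise_sd_log = 0.01, seed = 5))
  expect_true(all(sim$truth$true_effect_nmd == 0))
  nmd <- sim$observations[sim$observations$reporter == "NMD", ]
  expect_equal(mean(log2(nmd$gfp / nmd$rfp)), -log2(3), tolerance = 0.01)

  sim10 <- generate_screen(screen_sim_config(
    n_plates = 1, frac_nmd_hits = 0.10, frac_opt_hits = 0,
    frac_shared_hits = 0, seed = 5))
  tr <- sim10$truth[!sim10$truth$is_border, ]
  n_nmd_only <- sum(tr$true_effect_nmd != 0 & tr$true_effect_opt == 0)
  expect_equal(n_nmd_only, round(0.10 * nrow(tr)))
  # border strains never carry an effect
  expect_true(all(sim10$truth$true_effect_nmd[sim10$truth$is_border] == 0))
})

test_that("with no artifact and no noise the aggregated ratio recovers truth exactly", {
  sim <- generate_screen(screen_sim_config(
    n_plates = 1, spatial_amplitude = 0, noise_sd_log = 0,
    frac_nmd_hits = 0.1, seed = 2))
  sc <- suppressMessages(normalize_screen(sim$observations))
  nmd <- sc[sc$reporter == "NMD", ]
  truth <- sim$truth[match(nmd$strain_id, sim$truth$strain_id), ]
  expect_equal(nmd$log2_ratio, -log2(3) + truth$true_effect_nmd,
               tolerance = 1e-12)
})

test_that("size outliers appear at the configured rate, strictly out of range", {
  sim <- small_screen(seed = 11, frac_size_outliers = 0.2)
  s <- sim$observations$size_px
  out <- s < 1500 | s > 6000
  expect_true(all(s[!out] > 1500 & s[!out] < 6000))
  expect_equal(mean(out), 0.2, tolerance = 0.03)
})

test_that("invalid screen configs name the offending field", {
  expect_error(screen_sim_config(rows = 31), "rows", class = "rsga_config_error")
  expect_error(screen_sim_config(frac_nmd_hits = 1.2), "frac_nmd_hits",
               class = "rsga_config_error")
  expect_error(screen_sim_config(frac_nmd_hits = 0.6, frac_opt_hits = 0.6),
               "frac_nmd_hits", class = "rsga_config_error")
  expect_error(flow_sim_config(strains = c(a = 0), control_strain = "b"),
               "control_strain", class = "rsga_config_error")
  expect_error(flow_sim_config(strains = c(1, 2)), "strains",
               class = "rsga_config_error")
})

test_that("flow generation is seeded and matches its nominal event count", {
  fc <- flow_sim_config(strains = c(his3 = 0, mut = 1), n_events = 500,
                        seed = 4)
  a <- generate_flow(fc)
  b <- generate_flow(fc)
  expect_identical(a, b)
  expect_equal(nrow(a), 2 * 3 * 500)
  expect_equal(unique(table(a$strain_id, a$replicate))[1], 500)
})

test_that("null flow shifts give fold changes near 1 and identity gives exactly 1", {
  fc <- flow_sim_config(strains = c(his3 = 0, a = 0, b = 0), seed = 21,
                        n_events = 5000)
  val <- strain_fold_change(summarize_sample(generate_flow(fc)), "his3")
  expect_equal(val$fold_change_vs_control, rep(1, 3), tolerance = 0.05)
  expect_equal(val$fold_change_vs_control[val$strain_id == "his3"], 1)
})

test_that("a planted log2 shift of 1 yields a fold change within 5% of 2 across seeds", {
  fcs <- vapply(1:100, function(s) {
    fc <- flow_sim_config(strains = c(his3 = 0, shifted = 1),
                          n_events = 10000, seed = s)
    val <- strain_fold_change(summarize_sample(generate_flow(fc)), "his3")
    val$fold_change_vs_control[val$strain_id == "shifted"]
  }, numeric(1))
  expect_true(all(abs(fcs / 2 - 1) < 0.05))
})
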