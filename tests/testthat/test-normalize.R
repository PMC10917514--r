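test_that("size cutoffs are strict: boundary colonies are retained", {
  obs <- toy_observations(gfp = rep(2, 4), rfp = rep(1, 4),
                          size = c(1499, 1500, 6000, 6001))
  kept <- suppressMessages(filter_colonies(obs))
  expect_setequal(kept$size_px, c(1500, 6000))
  excl <- attr(kept, "exclusions")
  expect_equal(excl$n[excl$reason == "size_low"], 1)
  expect_equal(excl$n[excl$reason == "size_high"], 1)
})

test_that("an all-border plate filters to nothing, loudly", {
  obs <- toy_observations(gfp = rep(1, 4), rfp = rep(1, 4), border = TRUE)
  expect_warning(kept <- suppressMessages(filter_colonies(obs)),
                 "no colonies retained")
  expect_equal(nrow(kept), 0)
  excl <- attr(kept, "exclusions")
  expect_equal(excl$reason, "border")
  expect_equal(excl$n, 4)
})

test_that("exclusion counts match generator truth on simulated plates", {
  sim <- small_screen(seed = 6, frac_size_outliers = 0.05)
  obs <- sim$observations[sim$observations$reporter == "NMD", ]
  kept <- suppressMessages(filter_colonies(obs))
  excl <- attr(kept, "exclusions")
  expect_equal(excl$n[excl$reason == "border"], sum(obs$is_border))
  planted_out <- sum(!obs$is_border & (obs$size_px < 1500 | obs$size_px > 6000))
  expect_equal(sum(excl$n[excl$reason %in% c("size_low", "size_high")]),
               planted_out)
  expect_equal(nrow(kept) + sum(excl$n), nrow(obs))
})

test_that("filtering is idempotent", {
  sim <- small_screen(seed = 8)
  once <- suppressMessages(filter_colonies(sim$observations))
  twice <- suppressMessages(filter_colonies(once))
  expect_equal(sum(attr(twice, "exclusions")$n), 0)
  attr(once, "exclusions") <- NULL
  attr(twice, "exclusions") <- NULL
  expect_equal(twice, once)
})

test_that("aggregation computes means, medians and the log2 ratio of means", {
  obs <- toy_observations(gfp = rep(2, 4), rfp = rep(1, 4),
                          strain = rep("a", 4))
  sc <- aggregate_strain(obs)
  expect_equal(sc$mean_gfp, 2)
  expect_equal(sc$mean_rfp, 1)
  expect_equal(sc$log2_ratio, 1)
  expect_equal(sc$n_colonies_used, 4L)

  obs2 <- toy_observations(gfp = c(1, 3), rfp = c(2, 2), strain = rep("b", 2))
  sc2 <- aggregate_strain(obs2)
  expect_equal(sc2$mean_gfp, 2)
  expect_equal(sc2$log2_ratio, 0)
  expect_equal(sc2$median_gfp, 2)
})

test_that("aggregation matches a brute-force recomputation and ignores order", {
  sim <- small_screen(seed = 13)
  obs <- suppressMessages(filter_colonies(
    sim$observations[sim$observations$reporter == "OPT", ]))
  sc <- aggregate_strain(obs)
  # independent recomputation with base R
  for (s in sample(sc$strain_id, 20)) {
    raw <- obs[obs$strain_id == s, ]
    expect_equal(sc$mean_gfp[sc$strain_id == s], sum(raw$gfp) / nrow(raw))
    expect_equal(sc$log2_ratio[sc$strain_id == s],
                 log(sum(raw$gfp) / sum(raw$rfp), base = 2))
    expect_equal(sc$median_rfp[sc$strain_id == s],
                 sort(raw$rfp)[ceiling(nrow(raw) / 2)] / 2 +
                   sort(raw$rfp)[nrow(raw) %/% 2 + 1] / 2)
  }
  shuffled <- obs[sample(nrow(obs)), ]
  sc2 <- aggregate_strain(shuffled)
  sc2 <- sc2[match(sc$strain_id, sc2$strain_id), ]
  expect_equal(sc2$mean_gfp, sc$mean_gfp)
  expect_equal(sc2$log2_ratio, sc$log2_ratio)
})

test_that("strains with nonpositive mean signal are flagged unusable, not zeroed", {
  obs <- toy_observations(gfp = c(0, 0, 2, 2), rfp = c(1, 1, 0, 0),
                          strain = c("a", "a", "b", "b"))
  sc <- aggregate_strain(obs)
  expect_false(any(sc$usable))
  expect_true(all(is.na(sc$log2_ratio)))
})

test_that("LOESS reproduces its own model class: constants and ramps vanish", {
  grid <- expand.grid(row = seq(1.5, 31.5, by = 2), col = seq(1.5, 47.5, by = 2))
  base <- toy_scores(rep(0, nrow(grid)))
  base$row <- grid$row
  base$col <- grid$col
  const <- base
  const$log2_ratio <- 0.7
  out <- loess_normalize_plate(const)
  expect_true(all(abs(out$loess_value) < 1e-9))
  ramp <- base
  ramp$log2_ratio <- 0.05 * ramp$col
  out2 <- loess_normalize_plate(ramp)
  expect_true(all(abs(out2$loess_value) < 1e-6))
  expect_true(all(out2$normalized))
})

test_that("LOESS removes a planted spatial field from the ratio", {
  sim <- generate_screen(screen_sim_config(
    n_plates = 1, frac_nmd_hits = 0, frac_opt_hits = 0, frac_shared_hits = 0,
    spatial_amplitude = 0.5, noise_sd_log = 0.05, seed = 17))
  sc <- suppressMessages(normalize_screen(sim$observations))
  sc <- dplyr::inner_join(sc, sim$spatial,
                          by = c("reporter", "plate_id", "strain_id"))
  nmd <- sc[sc$reporter == "NMD" & sc$usable, ]
  expect_gt(cor(nmd$log2_ratio, nmd$field_ratio), 0.9)
  expect_lt(abs(cor(nmd$loess_value, nmd$field_ratio)), 0.1)
  expect_lt(var(nmd$loess_value), var(nmd$log2_ratio))
  expect_lt(abs(mean(nmd$loess_value)), 0.01)
})

test_that("the fitted surface depends on positions and values, not labels", {
  sim <- small_screen(seed = 19)
  sc <- aggregate_strain(suppressMessages(filter_colonies(
    sim$observations[sim$observations$reporter == "NMD", ])))
  out <- loess_normalize_plate(sc)
  permuted <- sc
  perm <- sample(nrow(sc))
  permuted$strain_id <- sc$strain_id[perm]
  permuted$gene_name <- sc$gene_name[perm]
  out2 <- loess_normalize_plate(permuted)
  expect_equal(out2$loess_value, out$loess_value)
})

test_that("without an artifact, normalization preserves the ratio distribution", {
  skip_if_not_installed("stats")
  pvals <- vapply(1:5, function(s) {
    sim <- generate_screen(screen_sim_config(
      n_plates = 1, spatial_amplitude = 0, noise_sd_log = 0.1,
      frac_nmd_hits = 0, frac_opt_hits = 0, frac_shared_hits = 0, seed = s))
    sc <- suppressMessages(normalize_screen(sim$observations))
    nmd <- sc[sc$reporter == "NMD" & sc$usable, ]
    suppressWarnings(stats::ks.test(nmd$loess_value,
                                    nmd$log2_ratio - mean(nmd$log2_ratio))$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("plates with too few points are skipped, flagged, and keep raw ratios", {
  sc <- toy_scores(c(0.1, 0.2, 0.3))
  expect_warning(out <- loess_normalize_plate(sc), "LOESS skipped")
  expect_false(any(out$normalized))
  expect_equal(out$loess_value, sc$log2_ratio)
})

test_that("normalization is strictly per plate", {
  sim <- small_screen(seed = 23, n_plates = 2)
  obs <- sim$observations[sim$observations$reporter == "NMD", ]
  all_sc <- suppressMessages(normalize_screen(obs))
  p1 <- obs[obs$plate_id == "plate01", ]
  solo <- suppressMessages(normalize_screen(p1))
  joint_p1 <- all_sc[all_sc$plate_id == "plate01", ]
  joint_p1 <- joint_p1[match(solo$strain_id, joint_p1$strain_id), ]
  expect_equal(joint_p1$loess_value, solo$loess_value)
})
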