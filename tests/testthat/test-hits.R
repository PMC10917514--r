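test_that("Z-scores use the population sd and standardize exactly", {
  sc <- toy_scores(c(-1, 0, 1))
  z <- zscore_screen(sc)$z
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)

  sim <- toy_scores(rnorm(200, mean = 3, sd = 2))
  z2 <- zscore_screen(sim)$z
  expect_lt(abs(mean(z2)), 1e-9)
  expect_lt(abs(sqrt(mean((z2 - mean(z2))^2)) - 1), 1e-9)
})

test_that("Z-scoring is affine-invariant under a shift and skips unusable strains", {
  sc <- toy_scores(rnorm(50, sd = 0.3))
  shifted <- sc
  shifted$loess_value <- sc$loess_value + 5
  expect_equal(zscore_screen(shifted)$z, zscore_screen(sc)$z)

  sc$usable[1:10] <- FALSE
  z <- zscore_screen(sc)$z
  expect_true(all(is.na(z[1:10])))
  expect_lt(abs(mean(z[-(1:10)])), 1e-9)
})

test_that("degenerate screens are rejected", {
  expect_error(zscore_screen(toy_scores(rep(0.5, 20))),
               class = "rsga_degenerate_error")
  expect_error(zscore_screen(toy_scores(c(1, 2))), "fewer than 3")
})

test_that("the hit definition separates reporter-specific from shared outliers", {
  nmd <- toy_scores(c(2.5, 2.5, -2.5, 0.3, 1.0) / 1)
  opt <- toy_scores(c(0.3, -2.5, 0.1, 2.6, 0.2))
  nmd$z <- nmd$loess_value
  opt$z <- opt$loess_value
  ht <- suppressMessages(call_hits(nmd, opt))
  expect_equal(ht$class, c("nmd_up", "shared", "nmd_down", "opt_only", "none"))
  expect_equal(ht$candidate, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # classes partition the joined universe
  expect_true(all(table(ht$gene_name) == 1))

  counts <- overlap_summary(ht)
  expect_equal(counts$nmd_up, 2)
  expect_equal(counts$nmd_down, 1)
  expect_equal(counts$opt_up, 1)
  expect_equal(counts$opt_down, 1)
  expect_equal(counts$nmd_only, 2)
  expect_equal(counts$opt_only, 1)
  expect_equal(counts$shared, 1)
  expect_equal(counts$candidates, 2)
})

test_that("overlap counts are order-invariant and satisfy the set identity", {
  set.seed(42)
  z1 <- rnorm(300, sd = 1.4)
  z2 <- rnorm(300, sd = 1.4)
  nmd <- toy_scores(z1); nmd$z <- z1
  opt <- toy_scores(z2); opt$z <- z2
  ht <- suppressMessages(call_hits(nmd, opt))
  a <- overlap_summary(ht)
  b <- overlap_summary(ht[sample(nrow(ht)), ])
  expect_equal(a, b)
  # NMD outliers minus shared equals the candidate count (brute force)
  n_nmd_outliers <- sum(abs(ht$z_nmd) > 2)
  expect_equal(n_nmd_outliers - a$shared, a$candidates)
  expect_equal(a$nmd_only, a$candidates)
})

test_that("raising the threshold never increases any outlier count", {
  set.seed(7)
  z1 <- rnorm(500, sd = 1.5)
  z2 <- rnorm(500, sd = 1.5)
  nmd <- toy_scores(z1); nmd$z <- z1
  opt <- toy_scores(z2); opt$z <- z2
  prev <- NULL
  for (thr in c(1, 1.5, 2, 2.5, 3)) {
    cur <- overlap_summary(suppressMessages(
      call_hits(nmd, opt, hit_config(z_threshold = thr))))
    if (!is.null(prev)) {
      for (f in c("nmd_up", "nmd_down", "opt_up", "opt_down", "candidates")) {
        expect_lte(cur[[f]], prev[[f]])
      }
    }
    prev <- cur
  }
})

test_that("duplicate strains collapse per policy before classification", {
  nmd <- toy_scores(c(2.5, -0.3, 1.0), genes = c("G1", "G1", "G2"))
  nmd$z <- nmd$loess_value
  opt <- toy_scores(c(0.1, 0.1, 0.1), genes = c("G1", "G1", "G2"))
  opt$z <- opt$loess_value
  ht <- suppressMessages(call_hits(nmd, opt))
  expect_equal(nrow(ht), 2)
  expect_equal(ht$z_nmd[ht$gene_name == "G1"], 2.5) # max |z| kept
  ht_first <- suppressMessages(
    call_hits(nmd, opt, hit_config(dedupe = "first")))
  expect_equal(ht_first$z_nmd[ht_first$gene_name == "G1"], 2.5)
  ht_mean <- suppressMessages(
    call_hits(nmd, opt, hit_config(dedupe = "mean")))
  expect_equal(ht_mean$z_nmd[ht_mean$gene_name == "G1"], (2.5 - 0.3) / 2)
})

test_that("genes absent from one screen are reported, never dropped silently", {
  nmd <- toy_scores(c(1, 2), genes = c("G1", "G2")); nmd$z <- nmd$loess_value
  opt <- toy_scores(c(1, 2), genes = c("G2", "G3")); opt$z <- opt$loess_value
  expect_message(ht <- call_hits(nmd, opt), "2 gene")
  expect_equal(ht$gene_name, "G2")
  expect_setequal(attr(ht, "unmatched")$gene_name, c("G1", "G3"))

  opt_disjoint <- toy_scores(1, genes = "G9"); opt_disjoint$z <- 1
  expect_error(suppressMessages(call_hits(nmd, opt_disjoint)),
               "share no genes")
})

test_that("hit counts from a two-reporter Z table match hand enumeration", {
  ztab <- tibble::tibble(
    gene_name = c("A", "B", "C", "D", "E", "E"),
    z_nmd = c(2.4, -3.0, 0.5, 2.1, 1.9, 2.2),
    z_opt = c(0.2, -2.2, 2.8, -0.4, 0.1, 0.3))
  counts <- hit_counts_from_zscores(ztab)
  # E deduplicates to |z| max 2.2
  expect_equal(counts$nmd_up, 3)   # A, D, E
  expect_equal(counts$nmd_down, 1) # B
  expect_equal(counts$opt_up, 1)   # C
  expect_equal(counts$opt_down, 1) # B
  expect_equal(counts$shared, 1)   # B
  expect_equal(counts$candidates, 3) # A, D, E
})

test_that("candidates export sorted by |z| with documented tie-breaks", {
  nmd <- toy_scores(c(2.5, -2.5, 3.5, 0.1), genes = c("GB", "GA", "GC", "GD"))
  nmd$z <- nmd$loess_value
  opt <- toy_scores(rep(0, 4), genes = c("GB", "GA", "GC", "GD"))
  opt$z <- opt$loess_value
  ht <- suppressMessages(call_hits(nmd, opt))
  path <- withr::local_tempfile(fileext = ".tsv")
  cand <- export_candidates(ht, path)
  expect_equal(cand$gene_name, c("GC", "GA", "GB"))
  on_disk <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(on_disk$gene_name, c("GC", "GA", "GB"))

  none <- ht[ht$gene_name == "GD", ]
  expect_warning(export_candidates(none, path), "no candidates")
  empty <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(empty), 0)
  expect_true("z_nmd" %in% names(empty))
})

test_that("planted hits stand out from the null strains in z", {
  sim <- generate_screen(screen_sim_config(
    n_plates = 1, frac_nmd_hits = 0.05, effect_size_log2 = 1,
    noise_sd_log = 0.1, seed = 31))
  sc <- suppressMessages(normalize_screen(
    sim$observations[sim$observations$reporter == "NMD", ]))
  z <- zscore_screen(sc)
  truth <- sim$truth[match(z$strain_id, sim$truth$strain_id), ]
  planted <- truth$true_effect_nmd != 0
  expect_gt(mean(abs(z$z[planted]), na.rm = TRUE),
            mean(abs(z$z[!planted]), na.rm = TRUE))
})
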