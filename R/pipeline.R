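#' Pipeline configuration
#'
#' Bundles the per-stage configurations for an end-to-end run. Exactly one
#' screen source must be given: a simulation config, a directory of raw
#' plate tables, or a pair of precomputed score tables (the latter starts the
#' run at the hit-calling stage). One named seed drives every source of
#' randomness; stage seeds are derived from it by fixed small offsets.
#'
#' @param screen_sim A [screen_sim_config()], or `NULL`.
#' @param screen_dir Directory in the layout of [write_screen()], or `NULL`.
#' @param nmd_scores_path,opt_scores_path Precomputed score TSVs
#'   (see [write_scores()]), or `NULL`.
#' @param filter A [filter_config()].
#' @param loess List of [loess_normalize_plate()] arguments.
#' @param hits A [hit_config()].
#' @param flow List: `enabled`, `n_strains` (candidates taken forward to the
#'   simulated flow validation), `n_events`, `n_replicates`, `lower_q`,
#'   `upper_q`, `test`. Flow validation runs only in simulation mode (it
#'   needs the ground-truth effects to assign flow shifts).
#' @param enrich List: `enabled`, `annotation` (data frame or path; in
#'   simulation mode a synthetic annotation with one term collecting the true
#'   NMD-effect genes plus random terms is built when none is given),
#'   `p_cutoff`, `n_random_terms`.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A validated list of class `rsga_pipeline_config`.
#' @export
pipeline_config <- function(screen_sim = NULL,
                            screen_dir = NULL,
                            nmd_scores_path = NULL,
                            opt_scores_path = NULL,
                            filter = filter_config(),
                            loess = list(span = 0.15, degree = 2,
                                         covariate = "2d"),
                            hits = hit_config(),
                            flow = list(enabled = TRUE, n_strains = 20,
                                        n_events = 10000, n_replicates = 3,
                                        lower_q = 0.05, upper_q = 0.95,
                                        test = "welch"),
                            enrich = list(enabled = TRUE, annotation = NULL,
                                          p_cutoff = 1e-7,
                                          n_random_terms = 20),
                            seed = 1L,
                            out_dir = tempfile("rsga_run_")) {
  has_scores <- !is.null(nmd_scores_path) || !is.null(opt_scores_path)
  n_sources <- (!is.null(screen_sim)) + (!is.null(screen_dir)) + has_scores
  if (n_sources != 1L) {
    stop_config("screen_sim",
                "exactly one screen source (screen_sim, screen_dir, or score tables) is required")
  }
  if (has_scores && (is.null(nmd_scores_path) || is.null(opt_scores_path))) {
    stop_config("nmd_scores_path", "both score tables are required")
  }
  if (!is.null(screen_sim) && !inherits(screen_sim, "rsga_screen_sim_config")) {
    stop_config("screen_sim", "must be created by screen_sim_config()")
  }
  if (!inherits(filter, "rsga_filter_config")) {
    stop_config("filter", "must be created by filter_config()")
  }
  if (!inherits(hits, "rsga_hit_config")) {
    stop_config("hits", "must be created by hit_config()")
  }
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(screen_sim = screen_sim, screen_dir = screen_dir,
         nmd_scores_path = nmd_scores_path,
         opt_scores_path = opt_scores_path,
         filter = filter, loess = loess, hits = hits, flow = flow,
         enrich = enrich, seed = as.integer(seed), out_dir = out_dir),
    class = "rsga_pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage `%s` failed: %s",
                         stage, conditionMessage(e)),
                 class = "rsga_stage_error", parent = e)
  })
}

# Hash of the scientific configuration only: the output location must not
# change the identity of a run.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(cfg, unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# Synthetic annotation for enrichment on simulated screens: one term holds
# the genes with a true NMD effect, the rest are random draws from the
# universe, so the enrichment stage has a planted positive and null terms.
simulate_annotation <- function(truth, universe, n_random_terms, seed) {
  withr::with_seed(seed, {
    true_term <- truth$gene_name[truth$true_effect_nmd != 0 & !truth$is_border]
    ann <- tibble::tibble(term = "TERM_TRUE_NMD",
                          gene = intersect(true_term, universe))
    for (i in seq_len(n_random_terms)) {
      sz <- sample(10:max(11, min(200, length(universe) %/% 5)), 1)
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        term = sprintf("TERM_RANDOM%02d", i),
        gene = sample(universe, min(sz, length(universe)))
      ))
    }
    ann
  })
}

#' Run the screen-analysis pipeline end to end
#'
#' Executes the configured stages — simulate (or load), filter/aggregate/
#' LOESS-normalize, Z-score and call hits, simulated flow validation of the
#' candidates, and term enrichment — writing every stage output plus a run
#' manifest (seed, config hash, per-stage row counts, file checksums) to the
#' output directory. Re-running with an identical config reproduces
#' identical outputs. Any stage error propagates with the stage name;
#' outputs of completed stages are preserved on disk.
#'
#' @param config A [pipeline_config()].
#' @return List with `scores_nmd`, `scores_opt`, `hit_table`, `overlap`,
#'   `candidates`, `validation` (or NULL), `enrichment` (or NULL), `truth`
#'   (simulation mode only), `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "rsga_pipeline_config")) {
    stop_config("config", "must be created by pipeline_config()")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  truth <- NULL

  if (!is.null(config$nmd_scores_path)) {
    scores <- run_stage("load_scores", {
      list(NMD = read_scores(config$nmd_scores_path),
           OPT = read_scores(config$opt_scores_path))
    })
  } else {
    if (!is.null(config$screen_sim)) {
      sim <- run_stage("simulate", {
        sim_cfg <- config$screen_sim
        sim_cfg$seed <- config$seed
        generate_screen(sim_cfg)
      })
      observations <- sim$observations
      truth <- sim$truth
      readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), na = "",
                       progress = FALSE)
    } else {
      loaded <- run_stage("load_screen", read_screen(config$screen_dir))
      observations <- loaded$observations
    }
    counts$observations <- nrow(observations)
    scores <- run_stage("normalize", {
      all_scores <- suppressMessages(rlang::exec(
        normalize_screen, observations, filter_cfg = config$filter,
        !!!config$loess))
      split(all_scores, all_scores$reporter)
    })
  }
  counts$scores_nmd <- nrow(scores$NMD)
  counts$scores_opt <- nrow(scores$OPT)

  hit_out <- run_stage("hits", {
    nmd_z <- zscore_screen(scores$NMD)
    opt_z <- zscore_screen(scores$OPT)
    write_scores(nmd_z, file.path(out_dir, "scores_nmd.tsv"))
    write_scores(opt_z, file.path(out_dir, "scores_opt.tsv"))
    hit_table <- suppressMessages(call_hits(nmd_z, opt_z, config$hits))
    readr::write_tsv(hit_table, file.path(out_dir, "hits.tsv"), na = "",
                     progress = FALSE)
    overlap <- overlap_summary(hit_table)
    jsonlite::write_json(overlap, file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE, digits = NA)
    candidates <- suppressWarnings(
      export_candidates(hit_table, file.path(out_dir, "candidates.tsv")))
    list(nmd_z = nmd_z, opt_z = opt_z, hit_table = hit_table,
         overlap = overlap, candidates = candidates)
  })
  counts$genes_joined <- nrow(hit_out$hit_table)
  counts$candidates <- nrow(hit_out$candidates)

  validation <- NULL
  if (isTRUE(config$flow$enabled) && !is.null(truth)) {
    validation <- run_stage("flow_validation", {
      cand <- head(hit_out$candidates$gene_name, config$flow$n_strains)
      shifts <- truth$true_effect_nmd[match(cand, truth$gene_name)]
      shifts[is.na(shifts)] <- 0
      strains <- c(stats::setNames(shifts, cand), his3 = 0)
      fc <- flow_sim_config(
        strains = strains, control_strain = "his3",
        n_events = config$flow$n_events,
        n_replicates = config$flow$n_replicates,
        seed = config$seed + 1L)
      events <- generate_flow(fc)
      gated <- gate_events(events, config$flow$lower_q, config$flow$upper_q)
      val <- strain_fold_change(summarize_sample(gated), "his3",
                                test = config$flow$test)
      readr::write_tsv(val, file.path(out_dir, "validation.tsv"), na = "",
                       progress = FALSE)
      val
    })
    counts$validated_strains <- nrow(validation)
  }

  enrichment <- NULL
  if (isTRUE(config$enrich$enabled)) {
    universe <- hit_out$hit_table$gene_name
    annotation <- config$enrich$annotation
    if (is.character(annotation) && length(annotation) == 1L) {
      annotation <- readr::read_tsv(annotation, progress = FALSE,
                                    show_col_types = FALSE)
    }
    if (is.null(annotation) && !is.null(truth)) {
      annotation <- simulate_annotation(
        truth, universe, config$enrich$n_random_terms %||% 20,
        config$seed + 2L)
    }
    if (!is.null(annotation) && nrow(hit_out$candidates) > 0) {
      enrichment <- run_stage("enrich", {
        res <- suppressMessages(hypergeom_enrich(
          hit_out$candidates$gene_name, annotation, universe,
          p_cutoff = config$enrich$p_cutoff %||% 1e-7))
        readr::write_tsv(res, file.path(out_dir, "enrichment.tsv"), na = "",
                         progress = FALSE)
        res
      })
      counts$enriched_terms <- nrow(enrichment)
    }
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "rsga",
    version = as.character(utils::packageVersion("rsga")),
    seed = config$seed,
    config_hash = config_hash(config),
    counts = counts,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(scores_nmd = hit_out$nmd_z, scores_opt = hit_out$opt_z,
       hit_table = hit_out$hit_table, overlap = hit_out$overlap,
       candidates = hit_out$candidates, validation = validation,
       enrichment = enrichment, truth = truth, manifest = manifest,
       out_dir = out_dir)
}
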