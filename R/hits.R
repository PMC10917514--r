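#' Z-score a screen
#'
#' Standardizes the LOESS-normalized log2 ratios over all usable strains of
#' the screen, pooled across plates (per-plate artifacts were already removed
#' by the per-plate normalization, so a single screen-wide scale is the
#' appropriate reference). Uses the population (n-denominator) standard
#' deviation; the resulting `z` has mean 0 and sd 1 over usable strains.
#'
#' @param scores Score tibble with `loess_value` (see [normalize_screen()]).
#' @param per_plate If `TRUE`, standardize within each plate instead of
#'   pooling (sensitivity analysis; default `FALSE`).
#' @return `scores` with a `z` column (NA for unusable strains).
#' @export
zscore_screen <- function(scores, per_plate = FALSE) {
  if (!"loess_value" %in% names(scores)) {
    stop_format("scores must carry `loess_value`; run the normalization first")
  }
  zfun <- function(df) {
    x <- df$loess_value
    ok <- !is.na(x) & df$usable
    if (sum(ok) < 3) {
      stop_format("fewer than 3 usable strains; cannot Z-score")
    }
    s <- sd_pop(x[ok])
    if (s == 0) {
      rlang::abort("degenerate screen: zero variance of normalized values",
                   class = "rsga_degenerate_error")
    }
    df$z <- ifelse(ok, (x - mean(x[ok])) / s, NA_real_)
    df
  }
  if (per_plate) {
    scores |>
      dplyr::group_by(.data$plate_id) |>
      dplyr::group_split() |>
      purrr::map(zfun) |>
      dplyr::bind_rows()
  } else {
    zfun(scores)
  }
}

#' Hit-calling configuration
#'
#' @param z_threshold Absolute Z-score above which a strain is an outlier in
#'   a screen (default 2.0).
#' @param dedupe How to collapse multiple strains mapping to one gene before
#'   classification: keep the record with maximal `|z|` (default), the first
#'   record, or the mean of the Z-scores.
#' @param same_sign_shared If `TRUE`, [overlap_summary()] counts a gene as
#'   shared between the screens only when its two Z-scores agree in sign
#'   (default `FALSE`: an outlier in both screens is shared regardless of
#'   direction).
#' @return A validated list of class `rsga_hit_config`.
#' @export
hit_config <- function(z_threshold = 2,
                       dedupe = c("max_abs_z", "first", "mean"),
                       same_sign_shared = FALSE) {
  check_number(z_threshold, "z_threshold", min = 0, strict_min = TRUE)
  dedupe <- match.arg(dedupe)
  if (!is.logical(same_sign_shared) || length(same_sign_shared) != 1L) {
    stop_config("same_sign_shared", "must be TRUE or FALSE")
  }
  structure(list(z_threshold = z_threshold, dedupe = dedupe,
                 same_sign_shared = same_sign_shared),
            class = "rsga_hit_config")
}

dedupe_genes <- function(scores, dedupe) {
  scores <- scores[!is.na(scores$z), , drop = FALSE]
  if (dedupe == "mean") {
    return(scores |>
             dplyr::group_by(.data$gene_name) |>
             dplyr::summarise(strain_id = .data$strain_id[1],
                              z = mean(.data$z), .groups = "drop"))
  }
  ord <- switch(dedupe,
    max_abs_z = order(scores$gene_name, -abs(scores$z), scores$strain_id),
    first = order(scores$gene_name, scores$strain_id)
  )
  scores <- scores[ord, , drop = FALSE]
  scores[!duplicated(scores$gene_name), c("gene_name", "strain_id", "z")]
}

#' Call reporter-specific hits against the control screen
#'
#' Joins the Z-scored NMD and OPT screens by gene, collapses duplicate
#' strains per gene, and classifies every gene. A gene is an NMD *candidate*
#' when its NMD-reporter Z-score is greater than the threshold or less than
#' its negative while its OPT-reporter Z-score is not also an outlier
#' (`|z_opt| <= threshold`): the control reporter removes strains that change
#' GFP/RFP for reasons unrelated to the premature stop codon (general
#' expression, fluorophore folding, growth).
#'
#' @param nmd_scores,opt_scores Z-scored score tibbles (see
#'   [zscore_screen()]) with `gene_name`, `strain_id`, `z`.
#' @param cfg A [hit_config()].
#' @return Tibble with one row per gene in both screens: `gene_name`,
#'   `strain_id`, `z_nmd`, `z_opt`, `class` (one of `nmd_up`, `nmd_down`,
#'   `shared`, `opt_only`, `none`) and logical `candidate`. Genes present in
#'   only one screen are reported in a message and attached as the
#'   `unmatched` attribute, never silently dropped.
#' @export
call_hits <- function(nmd_scores, opt_scores, cfg = hit_config()) {
  if (!inherits(cfg, "rsga_hit_config")) {
    stop_config("cfg", "must be created by hit_config()")
  }
  nmd <- dedupe_genes(nmd_scores, cfg$dedupe)
  opt <- dedupe_genes(opt_scores, cfg$dedupe)
  common <- intersect(nmd$gene_name, opt$gene_name)
  if (length(common) == 0) {
    stop_format("the NMD and OPT screens share no genes")
  }
  unmatched <- dplyr::bind_rows(
    tibble::tibble(gene_name = setdiff(nmd$gene_name, common), screen = "NMD"),
    tibble::tibble(gene_name = setdiff(opt$gene_name, common), screen = "OPT")
  )
  if (nrow(unmatched) > 0) {
    message(sprintf("call_hits: %d gene(s) present in only one screen",
                    nrow(unmatched)))
  }
  thr <- cfg$z_threshold
  joined <- dplyr::inner_join(
    dplyr::rename(nmd, z_nmd = "z"),
    dplyr::rename(opt[, c("gene_name", "z")], z_opt = "z"),
    by = "gene_name"
  )
  hit_nmd <- abs(joined$z_nmd) > thr
  hit_opt <- abs(joined$z_opt) > thr
  joined$class <- dplyr::case_when(
    hit_nmd & hit_opt ~ "shared",
    joined$z_nmd > thr ~ "nmd_up",
    joined$z_nmd < -thr ~ "nmd_down",
    hit_opt ~ "opt_only",
    TRUE ~ "none"
  )
  joined$candidate <- hit_nmd & !hit_opt
  attr(joined, "unmatched") <- unmatched
  attr(joined, "cfg") <- cfg
  joined
}

#' Overlap accounting over a classified hit table
#'
#' Counts, after duplicate-gene removal (already done by [call_hits()]):
#' outliers specific to each screen, the shared overlap, the per-direction
#' NMD and OPT outlier totals, and the size of the NMD candidate list.
#'
#' @param hit_table Output of [call_hits()].
#' @return Named list of counts: `nmd_up`, `nmd_down`, `opt_up`, `opt_down`
#'   (all outliers per reporter and direction, shared included), `nmd_only`,
#'   `opt_only`, `shared`, `candidates`.
#' @export
overlap_summary <- function(hit_table) {
  cfg <- attr(hit_table, "cfg") %||% hit_config()
  thr <- cfg$z_threshold
  hit_nmd <- abs(hit_table$z_nmd) > thr
  hit_opt <- abs(hit_table$z_opt) > thr
  shared <- hit_nmd & hit_opt
  if (isTRUE(cfg$same_sign_shared)) {
    shared <- shared & sign(hit_table$z_nmd) == sign(hit_table$z_opt)
  }
  list(
    nmd_up = sum(hit_table$z_nmd > thr),
    nmd_down = sum(hit_table$z_nmd < -thr),
    opt_up = sum(hit_table$z_opt > thr),
    opt_down = sum(hit_table$z_opt < -thr),
    nmd_only = sum(hit_nmd & !shared),
    opt_only = sum(hit_opt & !shared),
    shared = sum(shared),
    candidates = sum(hit_table$candidate)
  )
}

#' Apply the hit definition to a two-reporter Z-score table
#'
#' Counts hits directly from a table of per-gene Z-scores for both reporters
#' (for example a deposited screen summary spreadsheet), independently of the
#' normalization pipeline: per-reporter up/down outlier counts, the
#' deduplicated overlap, and the NMD-specific candidate-list size.
#'
#' @param ztable Data frame with columns `gene_name`, `z_nmd`, `z_opt`
#'   (rows with a missing Z-score in a reporter are excluded from that
#'   reporter's counts and from the joint counts).
#' @param z_threshold Outlier threshold (default 2.0).
#' @param dedupe Duplicate-gene policy, as in [hit_config()].
#' @return Named list of counts as in [overlap_summary()].
#' @export
hit_counts_from_zscores <- function(ztable, z_threshold = 2,
                                    dedupe = "max_abs_z") {
  stopifnot(all(c("gene_name", "z_nmd", "z_opt") %in% names(ztable)))
  if (!"strain_id" %in% names(ztable)) ztable$strain_id <- ztable$gene_name
  cfg <- hit_config(z_threshold = z_threshold, dedupe = dedupe)
  nmd <- ztable[, c("gene_name", "strain_id")]
  nmd$z <- ztable$z_nmd
  opt <- ztable[, c("gene_name", "strain_id")]
  opt$z <- ztable$z_opt
  hit_table <- suppressMessages(call_hits(nmd, opt, cfg))
  overlap_summary(hit_table)
}

#' Export the validation candidate list
#'
#' Writes the NMD-specific candidates sorted by decreasing `|z_nmd|`, ties
#' broken by gene name, as a TSV.
#'
#' @param hit_table Output of [call_hits()].
#' @param path Output path.
#' @return The candidate tibble, invisibly.
#' @export
export_candidates <- function(hit_table, path) {
  cand <- hit_table[hit_table$candidate, , drop = FALSE]
  cand <- cand[order(-abs(cand$z_nmd), cand$gene_name), , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("export_candidates: no candidates to export", call. = FALSE)
  }
  readr::write_tsv(
    cand[, c("gene_name", "strain_id", "z_nmd", "z_opt", "class")],
    path, na = "", progress = FALSE)
  invisible(cand)
}
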