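# Shared fixtures: all synthetic, built in code at test time.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small but structurally complete dual-reporter screen: 1536-format plates,
# 2x2 replicate blocks, border ring.
small_screen <- function(seed = 1, n_plates = 1, ...) {
  generate_screen(screen_sim_config(n_plates = n_plates, seed = seed, ...))
}

# Minimal colony observation tibble with explicit values, one plate.
toy_observations <- function(gfp, rfp, size = 3000, strain = NULL,
                             border = FALSE) {
  n <- length(gfp)
  k <- ceiling(sqrt(n))
  pos <- expand.grid(col = seq_len(k), row = seq_len(k))[seq_len(n), ]
  tibble::tibble(
    plate_id = "p1", reporter = "NMD",
    row = pos$row, col = pos$col,
    gfp = gfp, rfp = rfp,
    size_px = rep_len(size, n),
    strain_id = strain %||% paste0("s", seq_len(n)),
    gene_name = toupper(strain %||% paste0("s", seq_len(n))),
    is_border = rep_len(border, n)
  )
}

# Score tibble ready for Z-scoring / hit calling.
toy_scores <- function(values, genes = NULL, usable = TRUE) {
  n <- length(values)
  tibble::tibble(
    strain_id = paste0("s", seq_len(n)),
    gene_name = genes %||% paste0("G", seq_len(n)),
    plate_id = "p1", reporter = "NMD",
    row = seq_len(n), col = 1,
    n_colonies_used = 4L,
    mean_gfp = 1, mean_rfp = 1, median_gfp = 1, median_rfp = 1,
    log2_ratio = values,
    usable = rep_len(usable, n),
    loess_value = values
  )
}

write_lines_tsv <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
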