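# Tabular interchange formats. The canonical dialect is tab-separated values
# with a mandatory header and 1-based (row, col) plate coordinates. Missing
# values are written as empty fields, never 0 (0 is a legitimate intensity).
# A `col_map` (canonical_name = file_column_name) accommodates the varying
# column spellings of Spotfinder/SGATools-style exports.

read_tsv_chr <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

apply_col_map <- function(tab, col_map, required, path) {
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      src <- col_map[[canonical]]
      if (!src %in% names(tab)) {
        stop_format("column `%s` (mapped to `%s`) not found in %s",
                    src, canonical, path)
      }
      names(tab)[names(tab) == src] <- canonical
    }
  }
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop_format("missing column(s) %s in %s",
                paste0("`", missing, "`", collapse = ", "), path)
  }
  tab
}

# Parse a character column to numeric. Empty fields become NA (missing);
# non-numeric non-empty entries are a format error naming the data row.
parse_numeric_col <- function(x, column, path) {
  x <- trimws(x)
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop_format("non-numeric value '%s' in column `%s`, data row %d of %s",
                x[bad[1]], column, bad[1], path)
  }
  out
}

#' Read a colony fluorescence grid table
#'
#' Reads one plate's fluorescence table: one data row per spot with 1-based
#' `row` and `col` coordinates and `gfp`/`rfp` intensities. The grid must be
#' complete over its `rows x cols` extent (inferred from the maxima unless
#' given); an absent position is a ragged-grid format error, while a blank
#' intensity cell is read as a missing value and flagged, never dropped.
#'
#' @param path Path to a tab-separated file with header columns `row`, `col`,
#'   `gfp`, `rfp` (or others, via `col_map`).
#' @param reporter Reporter label to attach (`"NMD"` or `"OPT"`).
#' @param plate_id Plate identifier to attach.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(gfp = "GFP_median")`.
#' @param rows,cols Expected grid extent; default inferred from the data.
#' @return Tibble of colony observations with columns `plate_id`, `reporter`,
#'   `row`, `col`, `gfp`, `rfp`, `size_px`, `strain_id`, `gene_name`,
#'   `is_border`, `is_missing`. The input row count is attached as attribute
#'   `n_input`.
#' @export
read_grid_table <- function(path, reporter, plate_id, col_map = NULL,
                            rows = NULL, cols = NULL) {
  reporter <- match.arg(toupper(reporter), c("NMD", "OPT"))
  tab <- read_tsv_chr(path)
  tab <- apply_col_map(tab, col_map, c("row", "col", "gfp", "rfp"), path)
  n_input <- nrow(tab)
  row_i <- parse_numeric_col(tab$row, "row", path)
  col_i <- parse_numeric_col(tab$col, "col", path)
  if (anyNA(row_i) || anyNA(col_i)) {
    stop_format("plate %s: missing row/col coordinate in %s", plate_id, path)
  }
  if (any(row_i < 1) || any(col_i < 1) ||
      any(row_i != round(row_i)) || any(col_i != round(col_i))) {
    stop_format("plate %s: coordinates must be positive integers in %s",
                plate_id, path)
  }
  gfp <- parse_numeric_col(tab$gfp, "gfp", path)
  rfp <- parse_numeric_col(tab$rfp, "rfp", path)
  neg <- which(gfp < 0 | rfp < 0)
  if (length(neg) > 0) {
    stop_format("plate %s: negative intensity at data row %d of %s",
                plate_id, neg[1], path)
  }
  dup <- duplicated(paste(row_i, col_i))
  if (any(dup)) {
    i <- which(dup)[1]
    stop_format("plate %s: duplicated position (%d, %d) at data row %d of %s",
                plate_id, row_i[i], col_i[i], i, path)
  }
  rows <- rows %||% max(row_i)
  cols <- cols %||% max(col_i)
  if (nrow(tab) != rows * cols) {
    want <- tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols))
    have <- paste(row_i, col_i)
    miss <- want[!paste(want$row, want$col) %in% have, ]
    stop_format(
      "plate %s: ragged grid in %s — %d of %d positions absent (first: row %d, col %d)",
      plate_id, path, nrow(miss), rows * cols, miss$row[1], miss$col[1])
  }
  out <- tibble::tibble(
    plate_id = plate_id, reporter = reporter,
    row = as.integer(row_i), col = as.integer(col_i),
    gfp = gfp, rfp = rfp,
    size_px = NA_real_, strain_id = NA_character_,
    gene_name = NA_character_, is_border = NA,
    is_missing = is.na(gfp) | is.na(rfp)
  )
  out <- dplyr::arrange(out, .data$row, .data$col)
  attr(out, "n_input") <- n_input
  out
}

#' Write a colony fluorescence grid table
#'
#' Inverse of [read_grid_table()] for a single plate and reporter; missing
#' intensities are written as empty fields.
#'
#' @param observations Colony observations for one plate/reporter.
#' @param path Output path.
#' @export
write_grid_table <- function(observations, path) {
  stopifnot(all(c("row", "col", "gfp", "rfp") %in% names(observations)))
  if (length(unique(observations$plate_id)) > 1) {
    stop_format("write_grid_table() writes one plate at a time")
  }
  readr::write_tsv(observations[, c("row", "col", "gfp", "rfp")], path,
                   na = "", progress = FALSE)
  invisible(path)
}

#' Join an SGATools-style colony-size table onto observations
#'
#' @param observations Colony observations (one plate).
#' @param size_table Path to a TSV with columns `row`, `col`, `size`, or an
#'   equivalent data frame.
#' @param col_map Optional column-name map (see [read_grid_table()]).
#' @return `observations` with `size_px` filled. Positions absent from the
#'   size table keep a missing size; their count is reported in a message and
#'   in the `n_size_missing` attribute. Positions in the size table that do
#'   not exist on the plate are a geometry error, as are duplicated positions.
#' @export
join_size_table <- function(observations, size_table, col_map = NULL) {
  if (is.character(size_table)) {
    path <- size_table
    tab <- read_tsv_chr(path)
    tab <- apply_col_map(tab, col_map, c("row", "col", "size"), path)
    tab <- tibble::tibble(
      row = parse_numeric_col(tab$row, "row", path),
      col = parse_numeric_col(tab$col, "col", path),
      size = parse_numeric_col(tab$size, "size", path)
    )
  } else {
    tab <- tibble::as_tibble(size_table)
    stopifnot(all(c("row", "col", "size") %in% names(tab)))
    path <- "<data frame>"
  }
  dup <- duplicated(paste(tab$row, tab$col))
  if (any(dup)) {
    i <- which(dup)[1]
    stop_format("duplicated position (%d, %d) in size table %s",
                tab$row[i], tab$col[i], path)
  }
  known <- paste(observations$row, observations$col)
  extra <- !paste(tab$row, tab$col) %in% known
  if (any(extra)) {
    i <- which(extra)[1]
    stop_format(
      "size table %s does not match plate geometry: position (%d, %d) not on plate",
      path, tab$row[i], tab$col[i])
  }
  if (any(tab$size < 0, na.rm = TRUE)) {
    stop_format("negative colony size in %s", path)
  }
  out <- dplyr::rows_update(
    dplyr::mutate(observations, size_px = NA_real_),
    tibble::tibble(row = as.integer(tab$row), col = as.integer(tab$col),
                   size_px = tab$size),
    by = c("row", "col"), unmatched = "error"
  )
  n_missing <- sum(is.na(out$size_px))
  if (n_missing > 0) {
    message(sprintf("join_size_table: %d position(s) without a colony size",
                    n_missing))
  }
  attr(out, "n_size_missing") <- n_missing
  out
}

#' Read or write a strain key
#'
#' A strain key maps `(plate_id, row, col)` to `(strain_id, gene_name,
#' is_border)`.
#'
#' @param path Path to a TSV with those five columns.
#' @return Tibble strain key.
#' @export
read_strain_key <- function(path) {
  tab <- read_tsv_chr(path)
  tab <- apply_col_map(tab, NULL,
                       c("plate_id", "row", "col", "strain_id",
                         "gene_name", "is_border"), path)
  out <- tibble::tibble(
    plate_id = tab$plate_id,
    row = as.integer(parse_numeric_col(tab$row, "row", path)),
    col = as.integer(parse_numeric_col(tab$col, "col", path)),
    strain_id = tab$strain_id,
    gene_name = tab$gene_name,
    is_border = toupper(tab$is_border) %in% c("TRUE", "T", "1")
  )
  dup <- duplicated(paste(out$plate_id, out$row, out$col))
  if (any(dup)) {
    stop_format("duplicated key position in %s", path)
  }
  out
}

#' @rdname read_strain_key
#' @param key Strain key tibble.
#' @export
write_strain_key <- function(key, path) {
  readr::write_tsv(
    key[, c("plate_id", "row", "col", "strain_id", "gene_name", "is_border")],
    path, na = "", progress = FALSE)
  invisible(path)
}

#' Attach strain identities to observations
#'
#' Every observed position must resolve in the key; unresolvable positions
#' are an error (silent dropping is never allowed).
#'
#' @param observations Colony observations.
#' @param key Strain key tibble (see [read_strain_key()]).
#' @return Observations with `strain_id`, `gene_name`, `is_border` filled.
#' @export
join_strain_key <- function(observations, key) {
  out <- dplyr::left_join(
    dplyr::select(observations, -dplyr::any_of(c("strain_id", "gene_name",
                                                 "is_border"))),
    key[, c("plate_id", "row", "col", "strain_id", "gene_name", "is_border")],
    by = c("plate_id", "row", "col")
  )
  if (anyNA(out$strain_id)) {
    i <- which(is.na(out$strain_id))[1]
    stop_format("position (%s, %d, %d) does not resolve in the strain key",
                out$plate_id[i], out$row[i], out$col[i])
  }
  out
}

#' Read or write a flow-cytometry event table
#'
#' The canonical flow input is a TSV with one row per event and columns
#' `size`, `gfp`, `rfp` (plus optional `strain_id`, `replicate`).
#'
#' @param path Path to the event TSV.
#' @param col_map Optional column-name map.
#' @return Tibble of events; the loaded row count is reported in a message.
#' @export
read_flow_events <- function(path, col_map = NULL) {
  tab <- read_tsv_chr(path)
  tab <- apply_col_map(tab, col_map, c("size", "gfp", "rfp"), path)
  out <- tibble::tibble(
    size = parse_numeric_col(tab$size, "size", path),
    gfp = parse_numeric_col(tab$gfp, "gfp", path),
    rfp = parse_numeric_col(tab$rfp, "rfp", path)
  )
  bad <- which(is.na(out$size) | is.na(out$gfp) | is.na(out$rfp))
  if (length(bad) > 0) {
    stop_format("missing channel value at data row %d of %s", bad[1], path)
  }
  for (extra in c("strain_id", "replicate")) {
    if (extra %in% names(tab)) out[[extra]] <- tab[[extra]]
  }
  if ("replicate" %in% names(out)) {
    out$replicate <- as.integer(parse_numeric_col(out$replicate, "replicate", path))
  }
  message(sprintf("read_flow_events: %d event(s) loaded from %s",
                  nrow(out), basename(path)))
  out
}

#' @rdname read_flow_events
#' @param events Event tibble.
#' @export
write_flow_events <- function(events, path) {
  keep <- intersect(c("strain_id", "replicate", "size", "gfp", "rfp"),
                    names(events))
  readr::write_tsv(events[, keep], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read or write a strain score table
#'
#' @param path Path to a score TSV as written by [write_scores()].
#' @return Tibble of strain scores.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}

#' @rdname read_scores
#' @param scores Score tibble (see [aggregate_strain()]).
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a simulated screen to a directory
#'
#' Materializes a [generate_screen()] result in the on-disk layout the
#' readers consume: one fluorescence grid and one size table per plate per
#' reporter, a shared strain key, and the ground-truth table.
#'
#' @param sim A `rsga_screen_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(sim, dir) {
  stopifnot(inherits(sim, "rsga_screen_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs <- sim$observations
  for (rep_name in unique(obs$reporter)) {
    for (p in unique(obs$plate_id)) {
      sub <- obs[obs$reporter == rep_name & obs$plate_id == p, ]
      write_grid_table(sub, file.path(dir, sprintf("%s_%s_fluor.tsv", rep_name, p)))
      readr::write_tsv(
        tibble::tibble(row = sub$row, col = sub$col, size = sub$size_px),
        file.path(dir, sprintf("%s_%s_size.tsv", rep_name, p)),
        na = "", progress = FALSE)
    }
  }
  write_strain_key(sim$key, file.path(dir, "strain_key.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), na = "",
                   progress = FALSE)
  invisible(dir)
}

#' Read a screen directory written by [write_screen()]
#'
#' @param dir Directory containing `<reporter>_<plate>_fluor.tsv`,
#'   `<reporter>_<plate>_size.tsv` and `strain_key.tsv`.
#' @return List with `observations` (keyed, with sizes) and `key`.
#' @export
read_screen <- function(dir) {
  key <- read_strain_key(file.path(dir, "strain_key.tsv"))
  fluor <- list.files(dir, pattern = "_fluor\\.tsv$", full.names = TRUE)
  if (length(fluor) == 0) stop_format("no *_fluor.tsv files in %s", dir)
  obs <- purrr::map(fluor, function(f) {
    parts <- strsplit(sub("_fluor\\.tsv$", "", basename(f)), "_")[[1]]
    rep_name <- parts[1]
    plate <- paste(parts[-1], collapse = "_")
    g <- read_grid_table(f, reporter = rep_name, plate_id = plate)
    join_size_table(g, file.path(dir, sprintf("%s_%s_size.tsv", rep_name, plate)))
  })
  observations <- join_strain_key(dplyr::bind_rows(obs), key)
  list(observations = observations, key = key)
}
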