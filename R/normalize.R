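#' Colony filter configuration
#'
#' Border strains sit on the outermost rows and columns of a plate and grow
#' larger because of the nutrient edge effect; colonies outside the pixel
#' range are unreliable quantifications (pinning failures, merged colonies).
#' Both are removed before any statistics. Size cutoffs are strict
#' inequalities: a colony of exactly `size_min` or `size_max` pixels is
#' retained.
#'
#' @param size_min,size_max Analysable colony-size range in pixels; colonies
#'   with `size < size_min` or `size > size_max` are excluded
#'   (defaults 1500 and 6000).
#' @param drop_border Whether to exclude border strains (default `TRUE`).
#' @return A validated list of class `rsga_filter_config`.
#' @export
filter_config <- function(size_min = 1500, size_max = 6000,
                          drop_border = TRUE) {
  check_number(size_min, "size_min", min = 0)
  check_number(size_max, "size_max")
  if (size_min >= size_max) stop_config("size_min", "must be < size_max")
  if (!is.logical(drop_border) || length(drop_border) != 1L) {
    stop_config("drop_border", "must be TRUE or FALSE")
  }
  structure(list(size_min = size_min, size_max = size_max,
                 drop_border = drop_border),
            class = "rsga_filter_config")
}

#' Filter colony observations
#'
#' Removes border strains, size outliers, colonies without a usable size, and
#' colonies with a missing intensity, in that order of precedence; every
#' exclusion is counted by reason, never dropped silently. Filtering is
#' idempotent.
#'
#' @param observations Colony observations; if `strain_id` is not yet filled,
#'   `key` is joined first.
#' @param key Optional strain key (see [join_strain_key()]).
#' @param cfg A [filter_config()].
#' @return The retained observations. The per-reason exclusion counts are
#'   attached as attribute `exclusions` (a tibble with columns `reason`,
#'   `n`) and reported in a message. An empty retained set is legal.
#' @export
filter_colonies <- function(observations, key = NULL, cfg = filter_config()) {
  if (!inherits(cfg, "rsga_filter_config")) {
    stop_config("cfg", "must be created by filter_config()")
  }
  obs <- observations
  if (!is.null(key)) obs <- join_strain_key(obs, key)
  if (!"strain_id" %in% names(obs) || anyNA(obs$is_border)) {
    stop_format("observations must carry strain identities; supply `key`")
  }
  reason <- rep(NA_character_, nrow(obs))
  if (cfg$drop_border) reason[obs$is_border] <- "border"
  miss_size <- is.na(reason) & is.na(obs$size_px)
  reason[miss_size] <- "size_missing"
  reason[is.na(reason) & obs$size_px < cfg$size_min] <- "size_low"
  reason[is.na(reason) & obs$size_px > cfg$size_max] <- "size_high"
  miss_int <- is.na(reason) & (is.na(obs$gfp) | is.na(obs$rfp))
  reason[miss_int] <- "intensity_missing"

  excl <- tibble::tibble(reason = reason[!is.na(reason)]) |>
    dplyr::count(.data$reason, name = "n")
  retained <- obs[is.na(reason), , drop = FALSE]
  message(sprintf(
    "filter_colonies: %d of %d colonies retained (%s)",
    nrow(retained), nrow(obs),
    if (nrow(excl) == 0) "no exclusions"
    else paste(sprintf("%s: %d", excl$reason, excl$n), collapse = ", ")))
  if (nrow(retained) == 0) {
    warning("filter_colonies: no colonies retained", call. = FALSE)
  }
  attr(retained, "exclusions") <- excl
  retained
}

#' Aggregate replicate colonies into per-strain scores
#'
#' Collapses the surviving replicate colonies of each strain (up to four) to
#' one score: means and medians of GFP and RFP, and
#' `log2_ratio = log2(mean_gfp / mean_rfp)` computed from the means. Medians
#' are carried for diagnostics only. The strain's plate position is the
#' centroid of its surviving colonies, used later as the LOESS covariate.
#' Strains with no surviving colonies on a plate never appear; strains whose
#' mean GFP or RFP is not positive are flagged unusable (`usable = FALSE`),
#' never coerced to zeros.
#'
#' @param observations Filtered colony observations.
#' @return Tibble with one row per (reporter, plate, strain): `strain_id`,
#'   `gene_name`, `plate_id`, `reporter`, `row`, `col`, `n_colonies_used`,
#'   `mean_gfp`, `mean_rfp`, `median_gfp`, `median_rfp`, `log2_ratio`,
#'   `usable`.
#' @export
aggregate_strain <- function(observations) {
  grp <- intersect(c("reporter", "plate_id", "strain_id", "gene_name"),
                   names(observations))
  if (!"strain_id" %in% grp) {
    stop_format("observations must carry strain identities")
  }
  observations |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      row = mean(.data$row),
      col = mean(.data$col),
      n_colonies_used = sum(!is.na(.data$gfp) & !is.na(.data$rfp)),
      mean_gfp = mean(.data$gfp),
      mean_rfp = mean(.data$rfp),
      median_gfp = median(.data$gfp),
      median_rfp = median(.data$rfp),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      log2_ratio = dplyr::if_else(
        .data$mean_gfp > 0 & .data$mean_rfp > 0,
        log2(.data$mean_gfp / .data$mean_rfp),
        NA_real_),
      usable = .data$n_colonies_used > 0 & !is.na(.data$log2_ratio)
    )
}

#' Per-plate LOESS normalization of log2 ratios
#'
#' Fits a locally weighted regression surface of `log2_ratio` over the
#' strain's plate position (block centroid row and column) with tricube
#' weights and robustness iterations, strictly within one plate, and returns
#' the residual as the normalized value:
#' `loess_value = log2_ratio - fitted`. This removes smooth within-plate
#' artifacts (uneven illumination, nutrient and temperature gradients) from
#' the ratio while leaving strain effects, which are spatially unstructured,
#' intact.
#'
#' @param scores Strain scores for a single plate and reporter
#'   (see [aggregate_strain()]).
#' @param span LOESS span (fraction of points in each local fit), default
#'   0.15 (about 46 strains per local fit on a 1536-format plate): edge
#'   gradients on colony arrays are steep, and wider windows leave
#'   field-shaped bias near the plate margins.
#' @param degree Local polynomial degree, default 2: plate artifacts on
#'   colony arrays are dome- or ramp-shaped, and a local-quadratic fit is
#'   needed to follow their curvature without leaving field-shaped residual
#'   bias.
#' @param covariate `"2d"` (default) fits over (row, col); `"col"` fits a 1-D
#'   smoother over column index only, for sensitivity analysis.
#' @param family `"symmetric"` (default) uses robustness iterations to
#'   downweight outliers — planted hits must not drag the surface;
#'   `"gaussian"` disables them.
#' @param iterations Total loess iterations when `family = "symmetric"`
#'   (default 3, i.e. two robustness reweightings).
#' @param min_points Minimum usable strains required to fit (default 10); a
#'   plate below the minimum is skipped with a warning and its raw
#'   `log2_ratio` is carried forward, flagged un-normalized.
#' @return `scores` with `loess_value` filled (NA for unusable strains) and a
#'   logical `normalized` column.
#' @export
loess_normalize_plate <- function(scores, span = 0.15, degree = 2,
                                  covariate = c("2d", "col"),
                                  family = c("symmetric", "gaussian"),
                                  iterations = 3, min_points = 10) {
  covariate <- match.arg(covariate)
  family <- match.arg(family)
  check_number(span, "span", min = 0, strict_min = TRUE)
  check_number(degree, "degree", min = 0, max = 2, integerish = TRUE)
  if (length(unique(scores$plate_id)) > 1) {
    stop_format("loess_normalize_plate() normalizes one plate at a time")
  }
  usable <- scores$usable & is.finite(scores$log2_ratio)
  scores$loess_value <- NA_real_
  n_use <- sum(usable)
  if (n_use < max(10, min_points)) {
    warning(sprintf(
      "plate %s: only %d usable strain(s); LOESS skipped, raw log2_ratio carried forward",
      scores$plate_id[1], n_use), call. = FALSE)
    scores$loess_value[usable] <- scores$log2_ratio[usable]
    scores$normalized <- FALSE
    return(scores)
  }
  dat <- scores[usable, c("row", "col", "log2_ratio")]
  fml <- if (covariate == "2d") log2_ratio ~ row + col else log2_ratio ~ col
  fit <- loess(fml, data = dat, span = span, degree = degree,
               family = family, normalize = TRUE,
               control = loess.control(surface = "direct",
                                       iterations = iterations))
  scores$loess_value[usable] <- dat$log2_ratio - as.numeric(predict(fit, dat))
  scores$normalized <- TRUE
  scores
}

#' Normalize one screen end to end
#'
#' Convenience wrapper: [filter_colonies()], [aggregate_strain()], then
#' [loess_normalize_plate()] independently on every (reporter, plate).
#'
#' @param observations Colony observations (keyed, with sizes).
#' @param key Optional strain key if observations are not yet keyed.
#' @param filter_cfg A [filter_config()].
#' @param ... Passed to [loess_normalize_plate()].
#' @return Score tibble across all plates with `loess_value` filled.
#' @export
normalize_screen <- function(observations, key = NULL,
                             filter_cfg = filter_config(), ...) {
  retained <- filter_colonies(observations, key = key, cfg = filter_cfg)
  scores <- aggregate_strain(retained)
  scores |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("reporter", "plate_id")))) |>
    dplyr::group_split() |>
    purrr::map(loess_normalize_plate, ...) |>
    dplyr::bind_rows()
}
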