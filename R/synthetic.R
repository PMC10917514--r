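#' Configuration for a simulated dual-reporter colony-array screen
#'
#' Defines the study conditions for a simulated reporter-SGA screen: a yeast
#' deletion collection arrayed in 1536 format (32 rows by 48 columns per
#' plate), each deletion strain pinned as a 2x2 block of four replicate
#' colonies, scored with two reporters — an NMD reporter carrying a premature
#' termination codon and a matched PTC-free OPT control reporter.
#'
#' Hit strains receive a true log2 shift of the GFP/RFP ratio in one or both
#' screens. A small set of "strong" strains (emulating the canonical NMD
#' factors UPF1/2/3, which show the largest deviations in real screens)
#' receives a larger, always-positive shift in the NMD screen only. Each
#' channel on each plate is additionally modulated by a smooth spatial
#' artifact (low-order polynomial plus an edge component) and by
#' multiplicative log-normal measurement noise.
#'
#' @param n_plates Number of plates; 16 plates at this geometry hold ~4.9k
#'   non-border strains, the scale of the non-essential deletion collection.
#' @param rows,cols Spot grid per plate; both must be even so that 2x2
#'   replicate blocks tile exactly. Defaults give the 1536 format.
#' @param frac_nmd_hits,frac_opt_hits,frac_shared_hits Proportions of
#'   non-border strains planted as NMD-only, OPT-only, and shared
#'   (both-reporter) hits. Their sum must be at most 1.
#' @param effect_size_log2 Magnitude of the true log2 ratio shift for planted
#'   hits; the sign is random per hit.
#' @param n_strong_hits Number of NMD-only strains given the larger
#'   `strong_effect_log2` shift (counted inside `frac_nmd_hits`).
#' @param strong_effect_log2 Effect for the strong strains; default twice
#'   `effect_size_log2`, always positive (loss of NMD raises GFP).
#' @param noise_sd_log Standard deviation, on the log2 scale, of the
#'   independent multiplicative noise applied to each channel of each colony.
#' @param spatial_amplitude Standard deviation, on the log2 scale, of the
#'   smooth per-plate per-channel spatial field. 0 disables the artifact.
#' @param size_mean,size_sd Colony-size distribution (pixels); regular
#'   colonies are drawn truncated to the analysable range (1500, 6000) pixels
#'   so that planted outliers are exactly the out-of-range colonies.
#' @param frac_size_outliers Proportion of colonies drawn strictly outside
#'   the 1500–6000 pixel range.
#' @param baseline_log2_ratio Named vector, baseline log2(GFP/RFP) per
#'   reporter. The NMD reporter default is `-log2(3)`: a PTC represses the
#'   reporter about 3-fold relative to the OPT construct.
#' @param baseline_rfp Baseline RFP intensity in arbitrary fluorimeter units.
#' @param seed Integer seed; identical configs produce identical output.
#'
#' @return A validated list of class `rsga_screen_sim_config`.
#' @seealso [generate_screen()]
#' @export
screen_sim_config <- function(n_plates = 16,
                              rows = 32,
                              cols = 48,
                              frac_nmd_hits = 0.03,
                              frac_opt_hits = 0.03,
                              frac_shared_hits = 0.01,
                              effect_size_log2 = 1,
                              n_strong_hits = 3,
                              strong_effect_log2 = 2 * effect_size_log2,
                              noise_sd_log = 0.1,
                              spatial_amplitude = 0.2,
                              size_mean = 3500,
                              size_sd = 600,
                              frac_size_outliers = 0.05,
                              baseline_log2_ratio = c(NMD = -log2(3), OPT = 0),
                              baseline_rfp = 10000,
                              seed = 1L) {
  check_number(n_plates, "n_plates", min = 1, integerish = TRUE)
  check_number(rows, "rows", min = 2, integerish = TRUE)
  check_number(cols, "cols", min = 2, integerish = TRUE)
  if (rows %% 2L != 0L) stop_config("rows", "must be even (2x2 replicate blocks)")
  if (cols %% 2L != 0L) stop_config("cols", "must be even (2x2 replicate blocks)")
  check_fraction(frac_nmd_hits, "frac_nmd_hits")
  check_fraction(frac_opt_hits, "frac_opt_hits")
  check_fraction(frac_shared_hits, "frac_shared_hits")
  if (frac_nmd_hits + frac_opt_hits + frac_shared_hits > 1) {
    stop_config("frac_nmd_hits", paste(
      "frac_nmd_hits + frac_opt_hits + frac_shared_hits must be <= 1"
    ))
  }
  check_number(effect_size_log2, "effect_size_log2")
  check_number(n_strong_hits, "n_strong_hits", min = 0, integerish = TRUE)
  check_number(strong_effect_log2, "strong_effect_log2")
  check_number(noise_sd_log, "noise_sd_log", min = 0)
  check_number(spatial_amplitude, "spatial_amplitude", min = 0)
  check_number(size_mean, "size_mean", min = 0, strict_min = TRUE)
  check_number(size_sd, "size_sd", min = 0, strict_min = TRUE)
  check_fraction(frac_size_outliers, "frac_size_outliers")
  if (!is.numeric(baseline_log2_ratio) ||
      !all(c("NMD", "OPT") %in% names(baseline_log2_ratio))) {
    stop_config("baseline_log2_ratio", "must be a numeric vector named NMD and OPT")
  }
  check_number(baseline_rfp, "baseline_rfp", min = 0, strict_min = TRUE)
  check_number(seed, "seed", integerish = TRUE)

  structure(
    list(
      n_plates = as.integer(n_plates), rows = as.integer(rows),
      cols = as.integer(cols),
      frac_nmd_hits = frac_nmd_hits, frac_opt_hits = frac_opt_hits,
      frac_shared_hits = frac_shared_hits,
      effect_size_log2 = effect_size_log2,
      n_strong_hits = as.integer(n_strong_hits),
      strong_effect_log2 = strong_effect_log2,
      noise_sd_log = noise_sd_log, spatial_amplitude = spatial_amplitude,
      size_mean = size_mean, size_sd = size_sd,
      frac_size_outliers = frac_size_outliers,
      baseline_log2_ratio = baseline_log2_ratio,
      baseline_rfp = baseline_rfp, seed = as.integer(seed)
    ),
    class = "rsga_screen_sim_config"
  )
}

# Smooth spatial artifact on the log2 scale: random low-order polynomial in
# normalized plate coordinates plus a radially decaying edge component,
# centred and rescaled so its per-plate standard deviation equals `amplitude`.
make_spatial_field <- function(rows, cols, amplitude) {
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  if (amplitude == 0) return(cbind(grid, field = 0))
  u <- 2 * (grid$row - 1) / (rows - 1) - 1
  v <- 2 * (grid$col - 1) / (cols - 1) - 1
  a <- rnorm(6)
  d_edge <- pmin(grid$row - 1, rows - grid$row, grid$col - 1, cols - grid$col)
  f <- a[1] * u + a[2] * v + a[3] * u * v + a[4] * u^2 + a[5] * v^2 +
    a[6] * exp(-d_edge / (0.25 * min(rows, cols)))
  f <- f - mean(f)
  s <- sd(f)
  if (s > 0) f <- f * amplitude / s
  cbind(grid, field = f)
}

# Colony sizes: regular colonies truncated-normal inside the open analysable
# range, planted outliers strictly outside it (half small, half large).
draw_sizes <- function(n, cfg) {
  out <- runif(n) < cfg$frac_size_outliers
  sizes <- numeric(n)
  n_reg <- sum(!out)
  if (n_reg > 0) {
    draw <- rnorm(n_reg, cfg$size_mean, cfg$size_sd)
    bad <- draw <= 1500 | draw >= 6000
    while (any(bad)) {
      draw[bad] <- rnorm(sum(bad), cfg$size_mean, cfg$size_sd)
      bad <- draw <= 1500 | draw >= 6000
    }
    sizes[!out] <- draw
  }
  n_out <- sum(out)
  if (n_out > 0) {
    small <- runif(n_out) < 0.5
    o <- numeric(n_out)
    o[small] <- runif(sum(small), 800, 1499)
    o[!small] <- runif(sum(!small), 6001, 7500)
    sizes[out] <- o
  }
  sizes
}

#' Simulate a dual-reporter colony-array screen
#'
#' Generates matched NMD- and OPT-reporter plate tables over one shared strain
#' layout, together with the strain key and the ground-truth effect table used
#' by recovery tests. For every colony,
#' `GFP = baseline_rfp * 2^(baseline + effect + field_gfp + noise)` and
#' `RFP = baseline_rfp * 2^(field_rfp + noise)`, all exponents on the log2
#' scale. Each channel carries its own smooth spatial field (fields are shared
#' by the four colonies of a block only through position, and differ between
#' plates and reporters), so the artifact survives into log2(GFP/RFP) as it
#' does on real plates, where the two fluorophores are scanned with different
#' lasers and filters.
#'
#' The outermost ring of 2x2 blocks on every plate is flagged as border;
#' border strains never carry a planted effect.
#'
#' @param config A [screen_sim_config()].
#' @return A list of class `rsga_screen_sim` with elements
#'   \describe{
#'     \item{observations}{tibble of colony observations, one row per spot per
#'       reporter: `plate_id`, `reporter`, `row`, `col`, `gfp`, `rfp`,
#'       `size_px`, `strain_id`, `gene_name`, `is_border`.}
#'     \item{key}{strain key tibble `(plate_id, row, col) -> (strain_id,
#'       gene_name, is_border)`.}
#'     \item{truth}{per-strain ground truth: `strain_id`, `gene_name`,
#'       `true_effect_nmd`, `true_effect_opt`, `is_border`, `is_strong`.}
#'     \item{spatial}{per-strain planted net ratio artifact
#'       (gfp field minus rfp field, averaged over the block) per reporter.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_screen <- function(config = screen_sim_config()) {
  if (!inherits(config, "rsga_screen_sim_config")) {
    stop_config("config", "must be created by screen_sim_config()")
  }
  cfg <- config
  withr::with_seed(cfg$seed, {
    brows <- cfg$rows %/% 2L
    bcols <- cfg$cols %/% 2L
    blocks <- tidyr::expand_grid(
      plate_id = sprintf("plate%02d", seq_len(cfg$n_plates)),
      block_row = seq_len(brows),
      block_col = seq_len(bcols)
    )
    blocks$is_border <- blocks$block_row == 1L | blocks$block_row == brows |
      blocks$block_col == 1L | blocks$block_col == bcols
    n_blocks <- nrow(blocks)
    idx <- seq_len(n_blocks)
    blocks$strain_id <- ifelse(
      blocks$is_border,
      sprintf("border%05d", cumsum(blocks$is_border)[idx]),
      sprintf("strain%05d", cumsum(!blocks$is_border)[idx])
    )
    blocks$gene_name <- toupper(blocks$strain_id)

    # Plant true effects on non-border strains.
    nb <- blocks$strain_id[!blocks$is_border]
    n_nb <- length(nb)
    n_nmd <- round(cfg$frac_nmd_hits * n_nb)
    n_opt <- round(cfg$frac_opt_hits * n_nb)
    n_shared <- round(cfg$frac_shared_hits * n_nb)
    n_strong <- min(cfg$n_strong_hits, n_nmd)
    picked <- sample(nb, n_nmd + n_opt + n_shared)
    nmd_only <- picked[seq_len(n_nmd)]
    opt_only <- picked[n_nmd + seq_len(n_opt)]
    shared <- picked[n_nmd + n_opt + seq_len(n_shared)]
    strong <- nmd_only[seq_len(n_strong)]

    truth <- tibble::tibble(
      strain_id = blocks$strain_id,
      gene_name = blocks$gene_name,
      true_effect_nmd = 0,
      true_effect_opt = 0,
      is_border = blocks$is_border,
      is_strong = blocks$strain_id %in% strong
    )
    sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
    m <- match(nmd_only, truth$strain_id)
    truth$true_effect_nmd[m] <- sgn(n_nmd) * cfg$effect_size_log2
    truth$true_effect_nmd[truth$is_strong] <- abs(cfg$strong_effect_log2)
    m <- match(opt_only, truth$strain_id)
    truth$true_effect_opt[m] <- sgn(n_opt) * cfg$effect_size_log2
    m <- match(shared, truth$strain_id)
    shared_effect <- sgn(n_shared) * cfg$effect_size_log2
    truth$true_effect_nmd[m] <- shared_effect
    truth$true_effect_opt[m] <- shared_effect

    # Expand blocks to the four colony positions.
    offsets <- tidyr::expand_grid(dr = 0:1, dc = 0:1)
    spots <- tidyr::crossing(blocks, offsets)
    spots$row <- (spots$block_row - 1L) * 2L + 1L + spots$dr
    spots$col <- (spots$block_col - 1L) * 2L + 1L + spots$dc

    key <- tibble::as_tibble(spots[, c("plate_id", "row", "col",
                                       "strain_id", "gene_name", "is_border")])
    key <- dplyr::arrange(key, .data$plate_id, .data$row, .data$col)

    plate_ids <- unique(blocks$plate_id)
    reporters <- c("NMD", "OPT")
    obs_list <- list()
    spatial_list <- list()
    for (rep_name in reporters) {
      effect <- if (rep_name == "NMD") truth$true_effect_nmd else truth$true_effect_opt
      eff_by_strain <- stats::setNames(effect, truth$strain_id)
      for (p in plate_ids) {
        pk <- key[key$plate_id == p, ]
        fg <- make_spatial_field(cfg$rows, cfg$cols, cfg$spatial_amplitude)
        fr <- make_spatial_field(cfg$rows, cfg$cols, cfg$spatial_amplitude)
        pk <- dplyr::left_join(pk, tibble::tibble(
          row = fg$row, col = fg$col,
          field_gfp = fg$field, field_rfp = fr$field
        ), by = c("row", "col"))
        n <- nrow(pk)
        base <- cfg$baseline_log2_ratio[[rep_name]]
        eff <- unname(eff_by_strain[pk$strain_id])
        gfp <- cfg$baseline_rfp *
          2^(base + eff + pk$field_gfp + rnorm(n, 0, cfg$noise_sd_log))
        rfp <- cfg$baseline_rfp *
          2^(pk$field_rfp + rnorm(n, 0, cfg$noise_sd_log))
        obs_list[[paste(rep_name, p)]] <- tibble::tibble(
          plate_id = p, reporter = rep_name,
          row = pk$row, col = pk$col,
          gfp = gfp, rfp = rfp,
          size_px = draw_sizes(n, cfg),
          strain_id = pk$strain_id, gene_name = pk$gene_name,
          is_border = pk$is_border
        )
        ratio_field <- pk$field_gfp - pk$field_rfp
        spatial_list[[paste(rep_name, p)]] <- tibble::tibble(
          plate_id = p, reporter = rep_name, strain_id = pk$strain_id,
          field_ratio = ratio_field
        ) |>
          dplyr::group_by(.data$plate_id, .data$reporter, .data$strain_id) |>
          dplyr::summarise(field_ratio = mean(.data$field_ratio), .groups = "drop")
      }
    }
    observations <- dplyr::bind_rows(obs_list) |>
      dplyr::arrange(.data$reporter, .data$plate_id, .data$row, .data$col)
    spatial <- dplyr::bind_rows(spatial_list)

    structure(
      list(observations = observations, key = key, truth = truth,
           spatial = spatial, config = cfg),
      class = "rsga_screen_sim"
    )
  })
}

#' Configuration for simulated flow-cytometry samples
#'
#' Emulates the validation workflow: each strain is grown and measured in
#' triplicate, 10,000 events per sample, with per-event forward-scatter
#' (size), GFP and RFP channels. A strain simulated with ratio shift `s` has
#' expected mean-GFP/mean-RFP equal to the control's ratio times `2^s`.
#'
#' @param strains Named numeric vector: true log2 GFP/RFP ratio shift per
#'   strain (the control's shift is typically 0).
#' @param control_strain Name of the control strain (the HIS3-deletion
#'   analogue); must appear in `strains`.
#' @param n_events Events collected per sample (default 10000).
#' @param n_replicates Independent biological replicates per strain
#'   (default 3).
#' @param event_cv_log2 Per-event log2-scale noise sd on each fluorescence
#'   channel (cell-to-cell spread).
#' @param rep_noise_sd_log2 Per-replicate log2-scale noise sd applied to each
#'   channel (day-to-day growth and instrument drift); kept small so that
#'   replicate fold changes concentrate tightly around the true shift.
#' @param baseline_gfp,baseline_rfp Channel baselines in instrument units.
#' @param size_meanlog,size_sdlog Log-normal parameters of the size channel.
#' @param seed Integer seed.
#' @return A validated list of class `rsga_flow_sim_config`.
#' @export
flow_sim_config <- function(strains = c(his3 = 0),
                            control_strain = "his3",
                            n_events = 10000,
                            n_replicates = 3,
                            event_cv_log2 = 0.35,
                            rep_noise_sd_log2 = 0.01,
                            baseline_gfp = 2000,
                            baseline_rfp = 4000,
                            size_meanlog = log(5000),
                            size_sdlog = 0.3,
                            seed = 1L) {
  if (!is.numeric(strains) || is.null(names(strains)) ||
      any(names(strains) == "")) {
    stop_config("strains", "must be a named numeric vector of log2 shifts")
  }
  if (anyDuplicated(names(strains))) {
    stop_config("strains", "must not contain duplicated strain names")
  }
  if (!is.character(control_strain) || length(control_strain) != 1L ||
      !control_strain %in% names(strains)) {
    stop_config("control_strain", "must name one of the simulated strains")
  }
  check_number(n_events, "n_events", min = 1, integerish = TRUE)
  check_number(n_replicates, "n_replicates", min = 1, integerish = TRUE)
  check_number(event_cv_log2, "event_cv_log2", min = 0)
  check_number(rep_noise_sd_log2, "rep_noise_sd_log2", min = 0)
  check_number(baseline_gfp, "baseline_gfp", min = 0, strict_min = TRUE)
  check_number(baseline_rfp, "baseline_rfp", min = 0, strict_min = TRUE)
  check_number(size_sdlog, "size_sdlog", min = 0)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(strains = strains, control_strain = control_strain,
         n_events = as.integer(n_events),
         n_replicates = as.integer(n_replicates),
         event_cv_log2 = event_cv_log2,
         rep_noise_sd_log2 = rep_noise_sd_log2,
         baseline_gfp = baseline_gfp, baseline_rfp = baseline_rfp,
         size_meanlog = size_meanlog, size_sdlog = size_sdlog,
         seed = as.integer(seed)),
    class = "rsga_flow_sim_config"
  )
}

#' Simulate flow-cytometry event tables
#'
#' @param config A [flow_sim_config()].
#' @return Tibble of events with columns `strain_id`, `replicate`, `size`,
#'   `gfp`, `rfp`; `n_events` rows per strain per replicate.
#' @export
generate_flow <- function(config = flow_sim_config()) {
  if (!inherits(config, "rsga_flow_sim_config")) {
    stop_config("config", "must be created by flow_sim_config()")
  }
  cfg <- config
  withr::with_seed(cfg$seed, {
    out <- list()
    for (s in names(cfg$strains)) {
      shift <- cfg$strains[[s]]
      for (r in seq_len(cfg$n_replicates)) {
        g_eff <- rnorm(1, 0, cfg$rep_noise_sd_log2)
        r_eff <- rnorm(1, 0, cfg$rep_noise_sd_log2)
        n <- cfg$n_events
        out[[paste(s, r)]] <- tibble::tibble(
          strain_id = s, replicate = r,
          size = exp(rnorm(n, cfg$size_meanlog, cfg$size_sdlog)),
          gfp = cfg$baseline_gfp *
            2^(shift + g_eff + rnorm(n, 0, cfg$event_cv_log2)),
          rfp = cfg$baseline_rfp *
            2^(r_eff + rnorm(n, 0, cfg$event_cv_log2))
        )
      }
    }
    dplyr::bind_rows(out)
  })
}
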