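#' Gate flow-cytometry events on the size channel
#'
#' Retains events whose size channel lies within the closed empirical
#' quantile band `[lower_q, upper_q]` of their own sample (type-7 quantiles,
#' inclusive bounds). When the event table carries `strain_id`/`replicate`
#' columns the gate is computed per sample. The gate emulates the
#' instrument-side size gating of the cytometer, which excludes debris and
#' clumps; the original instrument gate is not recoverable, so a symmetric
#' quantile band is used.
#'
#' @param events Event tibble with a `size` column (see
#'   [read_flow_events()] or [generate_flow()]).
#' @param lower_q,upper_q Quantile bounds, `0 <= lower_q < upper_q <= 1`
#'   (defaults 0.05 and 0.95).
#' @return Gated events; the per-sample gate log (totals, gated counts,
#'   gate fraction) is attached as attribute `gate_log`.
#' @export
gate_events <- function(events, lower_q = 0.05, upper_q = 0.95) {
  check_number(lower_q, "lower_q", min = 0, max = 1)
  check_number(upper_q, "upper_q", min = 0, max = 1)
  if (lower_q >= upper_q) stop_config("lower_q", "must be < upper_q")
  grp <- intersect(c("strain_id", "replicate"), names(events))
  gate_one <- function(df) {
    qs <- quantile(df$size, c(lower_q, upper_q), type = 7, names = FALSE)
    kept <- df[df$size >= qs[1] & df$size <= qs[2], , drop = FALSE]
    if (nrow(kept) == 0) {
      lab <- if (length(grp) > 0) {
        paste(unlist(df[1, grp]), collapse = "/")
      } else "<sample>"
      stop_format("empty gate for sample %s", lab)
    }
    attr(kept, "n_total") <- nrow(df)
    kept
  }
  if (length(grp) == 0) {
    out <- gate_one(events)
    log <- tibble::tibble(n_total = attr(out, "n_total"), n_gated = nrow(out))
  } else {
    pieces <- events |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::group_split() |>
      purrr::map(gate_one)
    log <- purrr::map(pieces, function(p) {
      cbind(tibble::as_tibble(p[1, grp]),
            tibble::tibble(n_total = attr(p, "n_total"), n_gated = nrow(p)))
    }) |> dplyr::bind_rows()
    out <- dplyr::bind_rows(pieces)
  }
  log$gate_fraction <- log$n_gated / log$n_total
  attr(out, "gate_log") <- log
  out
}

#' Summarize a gated flow sample
#'
#' Arithmetic means of the GFP and RFP channels and their ratio for each
#' sample (each `strain_id`/`replicate` combination, or the whole table when
#' those columns are absent).
#'
#' @param events Gated event tibble (see [gate_events()]).
#' @return Tibble with one row per sample: `n_events_total` (if known from
#'   the gate log), `n_events_gated`, `mean_gfp`, `mean_rfp`, `ratio`, and a
#'   `usable` flag (`FALSE` when `mean_rfp` is not positive; the ratio is
#'   then NA, never a coerced number).
#' @export
summarize_sample <- function(events) {
  grp <- intersect(c("strain_id", "replicate"), names(events))
  gate_log <- attr(events, "gate_log")
  out <- events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_events_gated = dplyr::n(),
      mean_gfp = mean(.data$gfp),
      mean_rfp = mean(.data$rfp),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio = dplyr::if_else(.data$mean_rfp > 0,
                             .data$mean_gfp / .data$mean_rfp, NA_real_),
      usable = .data$mean_rfp > 0
    )
  if (!is.null(gate_log) && length(grp) > 0) {
    out <- dplyr::left_join(out,
                            gate_log[, c(grp, "n_total")],
                            by = grp)
    names(out)[names(out) == "n_total"] <- "n_events_total"
  } else if (!is.null(gate_log)) {
    out$n_events_total <- gate_log$n_total[1]
  }
  out
}

#' Fold changes of replicate flow samples against a control strain
#'
#' For each strain, averages the per-replicate GFP/RFP ratios and divides by
#' the control strain's average replicate ratio (mean of per-replicate
#' ratios, not ratio of pooled means); reports the log2 of that fraction and
#' a two-sample p-value comparing the strain's replicate ratios with the
#' control's.
#'
#' @param summaries Per-replicate sample summaries (see
#'   [summarize_sample()]) with `strain_id`, `replicate`, `ratio`.
#' @param control_strain Identifier of the control strain (e.g. the
#'   HIS3-deletion control); must have at least 2 usable replicates.
#' @param test Two-sample test on replicate ratios: `"welch"` (default,
#'   unequal-variance t-test), `"student"` or `"wilcoxon"`. Identical
#'   constant samples give p = 1, never an error.
#' @return Tibble with one row per strain: `strain_id`, `n_replicates`,
#'   `mean_ratio`, `fold_change_vs_control`, `log2_fold_change`, `p_value`.
#'   Strains with fewer than 2 usable replicates get an NA p-value and a
#'   warning.
#' @export
strain_fold_change <- function(summaries, control_strain,
                               test = c("welch", "student", "wilcoxon")) {
  test <- match.arg(test)
  s <- summaries[summaries$usable, , drop = FALSE]
  ctrl <- s$ratio[s$strain_id == control_strain]
  if (length(ctrl) == 0) {
    stop_format("control strain `%s` not present in the summaries",
                control_strain)
  }
  if (length(ctrl) < 2) {
    stop_format("control strain `%s` has fewer than 2 usable replicates",
                control_strain)
  }
  ctrl_mean <- mean(ctrl)
  out <- s |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      p_value = if (dplyr::n() >= 2) {
        two_sample_p(.data$ratio, ctrl, test = test)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold_change_vs_control = .data$mean_ratio / ctrl_mean,
      log2_fold_change = log2(.data$fold_change_vs_control)
    )
  if (any(out$n_replicates < 2)) {
    warning(sprintf("%d strain(s) with fewer than 2 usable replicates: p-value set to NA",
                    sum(out$n_replicates < 2)), call. = FALSE)
  }
  out[, c("strain_id", "n_replicates", "mean_ratio",
          "fold_change_vs_control", "log2_fold_change", "p_value")]
}
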