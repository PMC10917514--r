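#' Hypergeometric term enrichment of a hit list
#'
#' Fixed-target enrichment: for each annotation term, the upper-tail
#' hypergeometric probability of drawing at least the observed number of
#' term genes when sampling the hit list from the gene universe (the genes
#' for which screen data were successfully acquired) without replacement.
#' No multiple-testing correction is applied, mirroring the screen's
#' Z-score analysis.
#'
#' @param hit_genes Character vector of hit gene names (duplicates are
#'   removed; hits outside the universe are reported and dropped from the
#'   test).
#' @param annotation Two-column data frame `(gene, term)`, or a named list of
#'   character vectors (term -> genes).
#' @param universe Character vector: every gene scored in the screen.
#' @param p_cutoff Terms with `p_value < p_cutoff` are flagged `significant`
#'   (default `1e-7`).
#' @return Tibble sorted by ascending p-value with columns `term_id`, `k`
#'   (hits in term), `K` (universe genes in term), `n` (hit-list size used),
#'   `N` (universe size), `p_value`, `significant`. Terms with no universe
#'   genes are excluded. Dropped out-of-universe hits are attached as the
#'   `dropped_hits` attribute.
#' @export
hypergeom_enrich <- function(hit_genes, annotation, universe,
                             p_cutoff = 1e-7) {
  if (is.list(annotation) && !is.data.frame(annotation)) {
    annotation <- tibble::tibble(
      term = rep(names(annotation), lengths(annotation)),
      gene = unlist(annotation, use.names = FALSE)
    )
  }
  annotation <- tibble::as_tibble(annotation)
  if (!all(c("gene", "term") %in% names(annotation))) {
    stop_format("annotation must have columns `gene` and `term`")
  }
  universe <- unique(universe)
  if (length(universe) == 0) stop_format("empty gene universe")
  hit_genes <- unique(hit_genes)
  if (length(hit_genes) == 0) stop_format("empty hit list")
  dropped <- setdiff(hit_genes, universe)
  if (length(dropped) > 0) {
    message(sprintf("hypergeom_enrich: %d hit gene(s) outside the universe dropped",
                    length(dropped)))
    hit_genes <- intersect(hit_genes, universe)
    if (length(hit_genes) == 0) {
      stop_format("no hit genes remain inside the universe")
    }
  }
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  annotation <- dplyr::distinct(annotation, .data$term, .data$gene)
  N <- length(universe)
  n <- length(hit_genes)
  out <- annotation |>
    dplyr::group_by(term_id = .data$term) |>
    dplyr::summarise(
      k = sum(.data$gene %in% hit_genes),
      K = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                       lower.tail = FALSE),
      significant = .data$p_value < p_cutoff
    ) |>
    dplyr::arrange(.data$p_value, .data$term_id)
  attr(out, "dropped_hits") <- dropped
  out
}
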