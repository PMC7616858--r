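#' Rank splice-disrupting control guides
#'
#' Control guides are designed with an external splice-disruption predictor
#' that reports, per guide, a cDNA disruption score `d` in \[0, 1\] and
#' editor-specific activity scores. The selection metric is
#' `m = d * (abe_score + cbe_score)`, and the top `per_gene_top_k` guides per
#' gene are retained, ranked by `m` descending with ties broken by
#' `guide_id`. The external scores are inputs; only the combination metric
#' and selection are computed here.
#'
#' @param records Tibble with columns `guide_id`, `gene_id`,
#'   `cdna_disruption` (d), `abe_score`, `cbe_score`.
#' @param per_gene_top_k Number of guides to keep per gene (default 3).
#' @return The selected records with a `metric` column, ordered by gene then
#'   descending metric.
#' @examples
#' rank_control_guides(tibble::tibble(
#'   guide_id = c("a", "b"), gene_id = "G1",
#'   cdna_disruption = c(0.5, 0.2), abe_score = c(0.3, 0.1),
#'   cbe_score = c(0.2, 0.9)
#' ), per_gene_top_k = 1)
#' @export
rank_control_guides <- function(records, per_gene_top_k = 3) {
  records <- as_tibble(records)
  req <- c("guide_id", "gene_id", "cdna_disruption", "abe_score", "cbe_score")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    abort(paste0("records lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  scores <- records[, c("cdna_disruption", "abe_score", "cbe_score")]
  if (any(!vapply(scores, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(scores)))) {
    abort("scores must be present and finite")
  }
  if (any(records$cdna_disruption < 0)) {
    abort("cdna_disruption scores must be non-negative")
  }
  records |>
    mutate(metric = cdna_disruption * (abe_score + cbe_score)) |>
    arrange(gene_id, desc(metric), guide_id) |>
    group_by(gene_id) |>
    slice_head(n = per_gene_top_k) |>
    ungroup()
}
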