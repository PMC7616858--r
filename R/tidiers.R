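#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy guide scores
#'
#' @param x A [score_guides()] result.
#' @param ... Unused.
#' @return A plain tibble of per-guide scores.
#' @method tidy guide_scores
#' @export
tidy.guide_scores <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' Per-screen scoring summary
#'
#' @param x A [score_guides()] result.
#' @param ... Unused.
#' @return One row per (cell_line, editor): guides scored, filter pass rate,
#'   l2fc spread, and the scoring parameters used.
#' @method glance guide_scores
#' @export
glance.guide_scores <- function(x, ...) {
  params <- attr(x, "params")
  as_tibble(x) |>
    group_by(cell_line, editor) |>
    summarise(
      n_guides = n(),
      n_pass = sum(pass_filter),
      sd_l2fc = sd(l2fc[pass_filter]),
      median_z = median(z[pass_filter]),
      .groups = "drop"
    ) |>
    mutate(pseudocount = params$pseudocount,
           min_t0_reads = params$min_t0_reads,
           center_z = params$center_z)
}

#' Tidy a residue map
#'
#' @param x A [build_residue_map()] result.
#' @param contributions If `TRUE` return the per-guide contributions instead
#'   of the per-residue aggregate.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy residue_map
#' @export
tidy.residue_map <- function(x, contributions = FALSE, ...) {
  if (contributions) return(attr(x, "contributions"))
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' Residue-map summary
#'
#' @param x A [build_residue_map()] result.
#' @param ... Unused.
#' @return One-row tibble: protein length, covered residues, hits, coverage
#'   fraction, hit threshold and aggregation used.
#' @export
glance.residue_map <- function(x, ...) {
  m <- as_tibble(x)
  tibble(
    protein_length = attr(x, "protein_length"),
    n_covered = sum(m$n_guides >= 1),
    coverage_fraction = mean(m$n_guides >= 1),
    n_hits = sum(m$hit, na.rm = TRUE),
    hit_z = attr(x, "hit_z"),
    aggregate = attr(x, "aggregate")
  )
}
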