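# Plain-text TSV interfaces. Every pipeline output carries a commented
# header block (package version + config hash) so a run can be audited and
# reproduced from its files alone.

write_tsv_with_header <- function(x, path, header = character()) {
  lines <- c(sprintf("# bescan %s", as.character(utils::packageVersion("bescan"))),
             paste0("# ", header))
  writeLines(lines, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read screen count and sample-sheet TSVs
#'
#' @param path TSV path. Counts: `guide_id` plus one integer column per
#'   sample. Sample sheet: `sample_id`, `cell_line`, `editor`, `timepoint`,
#'   `replicate`.
#' @return A tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' @rdname read_counts
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", cell_line = "c", editor = "c",
                    timepoint = "c", replicate = "i"
                  ))
}

# predictions with list-columns flattened to strings
flatten_predictions <- function(predictions) {
  p <- as_tibble(predictions)
  tibble(
    guide_id = p$guide_id, category = p$category, editor = p$editor,
    mode = p$mode, n_edits = p$n_edits,
    edits = edits_to_string(p$edits),
    consequence = p$consequence,
    protein_changes = protein_changes_to_string(p$protein_changes),
    installs_proline = p$installs_proline,
    splice_residue = p$splice_residue
  )
}
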