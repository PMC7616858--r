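# Project guide-level depletion z-scores onto protein residues, call hits,
# and test domain / pathogenicity-class enrichment.

#' Build a per-residue essentiality map
#'
#' Each passing guide with a protein-altering consequence (missense,
#' nonsense, start_loss, stop_loss) contributes its z-score to every residue
#' in its predicted protein changes; splice-disrupting guides contribute to
#' the nearest exonic residue flanking the affected intron boundary.
#' Synonymous, intronic, promoter and no-edit guides contribute to no
#' residue. Per residue the aggregate is the minimum contributing z by
#' default (a single strongly depleted guide marks a residue intolerant);
#' `aggregate = "mean"` is available. A residue is a hit iff its aggregate z
#' is at or below `hit_z` and it has at least one contributing guide;
#' residues with no contributing guide carry `NA` (no evidence), which is
#' distinct from "not a hit".
#'
#' @param scores A [score_guides()] result (any number of screens; all
#'   passing guides contribute).
#' @param predictions Classified combined-mode predictions
#'   ([annotate_guides()]), matched to `scores` by `guide_id` and `editor`.
#' @param protein_length Protein length in residues (stop codon excluded).
#' @param hit_z Hit threshold on the aggregate z (default -2).
#' @param aggregate `"min"` (default) or `"mean"`.
#' @return A `residue_map` tibble with one row per residue 1..protein_length:
#'   `residue`, `n_guides`, `aggregate_z`, `hit`, plus a `contributions`
#'   attribute (tibble of guide-residue contributions).
#' @export
build_residue_map <- function(scores, predictions, protein_length,
                              hit_z = -2, aggregate = c("min", "mean")) {
  aggregate <- arg_match(aggregate)
  protein_length <- as.integer(protein_length)
  preds <- as_tibble(predictions)
  if (!all(preds$mode == "combined")) {
    abort("predictions must be combined-mode")
  }
  if (any(is.na(preds$consequence))) {
    abort("predictions must be classified (run classify_consequence)")
  }
  sc <- as_tibble(scores) |> filter(pass_filter)

  joined <- inner_join(
    sc[, c("cell_line", "editor", "guide_id", "z")],
    preds[, c("guide_id", "editor", "consequence", "protein_changes",
              "splice_residue")],
    by = c("guide_id", "editor"), relationship = "many-to-many"
  )

  protein_rows <- joined$consequence %in%
    c("missense", "nonsense", "start_loss", "stop_loss")
  splice_rows <- joined$consequence %in% c("splice_donor", "splice_acceptor") &
    !is.na(joined$splice_residue)

  contrib <- list()
  if (any(protein_rows)) {
    pr <- joined[protein_rows, ]
    n_res <- vapply(pr$protein_changes, nrow, integer(1))
    contrib$protein <- tibble(
      residue = unlist(lapply(pr$protein_changes, `[[`, "residue"),
                       use.names = FALSE),
      guide_id = rep.int(pr$guide_id, n_res),
      cell_line = rep.int(pr$cell_line, n_res),
      editor = rep.int(pr$editor, n_res),
      z = rep.int(pr$z, n_res),
      consequence = rep.int(pr$consequence, n_res)
    )
  }
  if (any(splice_rows)) {
    sr <- joined[splice_rows, ]
    contrib$splice <- tibble(
      residue = sr$splice_residue, guide_id = sr$guide_id,
      cell_line = sr$cell_line, editor = sr$editor, z = sr$z,
      consequence = sr$consequence
    )
  }
  contrib <- bind_rows(contrib)

  if (nrow(contrib) > 0) {
    # the stop codon (residue protein_length + 1) folds onto the last residue
    contrib$residue[contrib$residue == protein_length + 1L] <- protein_length
    if (any(contrib$residue > protein_length)) {
      abort("protein_change residue beyond protein length")
    }

    agg_fun <- if (aggregate == "min") min else mean
    per_res <- contrib |>
      group_by(residue) |>
      summarise(n_guides = n(), aggregate_z = agg_fun(z), .groups = "drop")
  } else {
    per_res <- tibble(residue = integer(), n_guides = integer(),
                      aggregate_z = double())
  }

  map <- tibble(residue = seq_len(protein_length)) |>
    left_join(per_res, by = "residue") |>
    mutate(
      n_guides = ifelse(is.na(n_guides), 0L, n_guides),
      hit = ifelse(n_guides >= 1, aggregate_z <= hit_z, NA)
    )
  structure(map, class = c("residue_map", class(map)),
            contributions = contrib, hit_z = hit_z, aggregate = aggregate,
            protein_length = protein_length)
}

#' Domain / pathogenicity-class hit enrichment
#'
#' One-sided hypergeometric test for over-representation of hit residues
#' within each label. The universe is restricted to guide-covered residues
#' (`n_guides >= 1`): uncovered residues are no evidence of tolerance.
#' Supply either a domain track (`label`, `start`, `end`; intervals may
#' overlap) or a per-residue pathogenicity track (`residue`, `class`), in
#' which case each class is tested as a label.
#'
#' @param map A [build_residue_map()] result.
#' @param track Domain tibble (`label`, `start`, `end`) or pathogenicity
#'   tibble (`residue`, `class`).
#' @return Tibble: `label`, `hits_in`, `covered_in`, `hits_out`,
#'   `covered_out`, `p_value`.
#' @export
domain_enrichment <- function(map, track) {
  map <- as_tibble(map)
  track <- as_tibble(track)
  universe <- map[map$n_guides >= 1, ]
  if (nrow(universe) == 0) abort("empty universe: no guide-covered residues")

  if (all(c("label", "start", "end") %in% names(track))) {
    labels <- unique(track$label)
    members <- lapply(labels, function(lb) {
      iv <- track[track$label == lb, ]
      unique(unlist(Map(seq.int, iv$start, iv$end), use.names = FALSE))
    })
  } else if (all(c("residue", "class") %in% names(track))) {
    labels <- unique(track$class)
    members <- lapply(labels, function(lb) track$residue[track$class == lb])
  } else {
    abort("track must have columns (label, start, end) or (residue, class)")
  }

  total_hits <- sum(universe$hit)
  n_universe <- nrow(universe)
  rows <- lapply(seq_along(labels), function(i) {
    inside <- universe$residue %in% members[[i]]
    covered_in <- sum(inside)
    covered_out <- n_universe - covered_in
    if (covered_in == 0 || covered_out == 0) {
      abort(sprintf(
        "label '%s' needs covered residues both inside and outside",
        labels[i]
      ))
    }
    hits_in <- sum(universe$hit[inside])
    tibble(
      label = labels[i],
      hits_in = hits_in, covered_in = covered_in,
      hits_out = total_hits - hits_in, covered_out = covered_out,
      p_value = phyper(hits_in - 1, total_hits, n_universe - total_hits,
                       covered_in, lower.tail = FALSE)
    )
  })
  bind_rows(rows)
}

#' Cross-screen concordance
#'
#' Pearson correlation of z-scores over the guides passing filters in both
#' screens.
#'
#' @param scores_a,scores_b Two [score_guides()] results (or any tibbles
#'   with `guide_id`, `pass_filter`, `z`).
#' @return Tibble with `r`, `r2`, `n_shared`.
#' @export
screen_concordance <- function(scores_a, scores_b) {
  a <- as_tibble(scores_a) |> filter(pass_filter) |> select(guide_id, z)
  b <- as_tibble(scores_b) |> filter(pass_filter) |> select(guide_id, z)
  shared <- inner_join(a, b, by = "guide_id", suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    abort(sprintf("only %d guides pass filters in both screens; need >= 3",
                  nrow(shared)))
  }
  r <- cor(shared$z_a, shared$z_b)
  tibble(r = r, r2 = r^2, n_shared = nrow(shared))
}
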