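# Raw sgRNA counts -> filtered, replicate-averaged, z-scored depletion.
#
# One screen = one cell line x one editor, with T0 and Tend timepoints and
# >= 1 replicate each. Counts arrive as a tibble with a guide_id column plus
# one integer column per sample; sample metadata is a separate sheet.

#' Scoring parameters
#'
#' @param pseudocount Positive pseudo-count added to raw counts before RPM
#'   normalization (default 1).
#' @param min_t0_reads Guides with mean raw T0 reads strictly below this are
#'   discarded ("fewer than" is strict: 100 passes, 99 fails; default 100).
#' @param center_z If `TRUE` (default) z-scores are mean-centred before
#'   dividing by the standard deviation; `FALSE` reproduces the literal
#'   "L2FC divided by its standard deviation".
#' @param hit_z Depletion z threshold used for hit calling downstream
#'   (default -2).
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(pseudocount = 1, min_t0_reads = 100,
                           center_z = TRUE, hit_z = -2) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("pseudocount must be > 0")
  }
  if (!is.numeric(min_t0_reads) || min_t0_reads < 0) {
    abort("min_t0_reads must be >= 0")
  }
  structure(list(pseudocount = pseudocount, min_t0_reads = min_t0_reads,
                 center_z = isTRUE(center_z), hit_z = hit_z),
            class = "scoring_params")
}

check_screen_tables <- function(counts, samples) {
  counts <- as_tibble(counts)
  samples <- as_tibble(samples)
  req <- c("sample_id", "cell_line", "editor", "timepoint", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    abort(paste0("sample sheet lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(samples$timepoint %in% c("T0", "Tend"))) {
    abort("timepoint must be 'T0' or 'Tend'")
  }
  missing_samples <- setdiff(samples$sample_id, names(counts))
  if (length(missing_samples)) {
    abort(paste0("counts lack sample column(s): ",
                 paste(missing_samples, collapse = ", ")))
  }
  if (anyDuplicated(counts$guide_id)) {
    abort("duplicate guide_id in counts")
  }
  cm <- as.matrix(counts[, samples$sample_id])
  if (any(cm < 0) || any(cm != round(cm))) {
    abort("counts must be non-negative integers")
  }
  list(counts = counts, samples = samples)
}

#' RPM-normalize and average replicates
#'
#' Per sample, `RPM_g = (count_g + c) / sum(count + c) * 1e6`; RPM values are
#' then averaged arithmetically across replicates within each
#' (cell line, editor, timepoint). Raw T0 means are carried along for the
#' read-count filter.
#'
#' @param counts Tibble: `guide_id` plus one column per `sample_id`.
#' @param samples Sample sheet tibble: `sample_id`, `cell_line`, `editor`,
#'   `timepoint` (`T0`/`Tend`), `replicate`.
#' @param params A [scoring_params()].
#' @return Tibble with `cell_line`, `editor`, `guide_id`, `mean_rpm_t0`,
#'   `mean_rpm_end`, `mean_raw_t0`.
#' @export
normalize_and_average <- function(counts, samples, params = scoring_params()) {
  ck <- check_screen_tables(counts, samples)
  counts <- ck$counts; samples <- ck$samples
  c0 <- params$pseudocount

  long <- counts |>
    tidyr::pivot_longer(dplyr::all_of(samples$sample_id),
                        names_to = "sample_id", values_to = "count") |>
    inner_join(samples, by = "sample_id") |>
    group_by(sample_id) |>
    mutate(rpm = (count + c0) / sum(count + c0) * 1e6) |>
    ungroup()

  long |>
    group_by(cell_line, editor, guide_id, timepoint) |>
    summarise(mean_rpm = mean(rpm), mean_raw = mean(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = timepoint,
                       values_from = c("mean_rpm", "mean_raw")) |>
    rename(mean_rpm_t0 = "mean_rpm_T0", mean_rpm_end = "mean_rpm_Tend",
           mean_raw_t0 = "mean_raw_T0") |>
    select(cell_line, editor, guide_id, mean_rpm_t0, mean_rpm_end, mean_raw_t0)
}

#' Score guide depletion
#'
#' Full scoring chain: RPM with pseudo-count, replicate averaging, the
#' minimum-T0-reads filter, per-guide `l2fc = log2(rpm_end / rpm_t0)`, and a
#' per-screen z-score `z = (l2fc - mean(l2fc)) / sd(l2fc)` over passing
#' guides (sample standard deviation; the mean term is dropped when
#' `center_z = FALSE`). Each (cell line, editor) screen is standardized
#' independently.
#'
#' @inheritParams normalize_and_average
#' @return A `guide_scores` tibble: `cell_line`, `editor`, `guide_id`,
#'   `mean_rpm_t0`, `mean_rpm_end`, `mean_raw_t0`, `pass_filter`, `l2fc`,
#'   `z` (`NA` for filtered guides), with the params stored as an attribute.
#' @export
score_guides <- function(counts, samples, params = scoring_params()) {
  avg <- normalize_and_average(counts, samples, params)
  scored <- avg |>
    group_by(cell_line, editor) |>
    group_modify(function(df, key) {
      df$pass_filter <- df$mean_raw_t0 >= params$min_t0_reads
      n_pass <- sum(df$pass_filter)
      if (n_pass < 3) {
        abort(sprintf(
          "screen %s/%s has %d guides passing the T0 filter; need >= 3",
          key$cell_line, key$editor, n_pass
        ))
      }
      df$l2fc <- ifelse(df$pass_filter,
                        log2(df$mean_rpm_end / df$mean_rpm_t0), NA_real_)
      lf <- df$l2fc[df$pass_filter]
      centre <- if (params$center_z) mean(lf) else 0
      df$z <- (df$l2fc - centre) / sd(lf)
      df
    }) |>
    ungroup()
  structure(scored, class = c("guide_scores", class(scored)),
            params = params)
}

# P(x < y) + 0.5 P(x = y), rank-based (Mann-Whitney)
auroc_lower <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(c(x, y))
  u_greater <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs x > y (+0.5 ties)
  1 - u_greater / (n1 * n2)
}

#' Control-based screen QC
#'
#' Per screen, reports the median z of each control category, the rank-based
#' AUROC separating essential-stop from non-essential-stop controls (the
#' probability that a random essential-stop control scores lower than a
#' random non-essential-stop control), and the non-targeting median z.
#'
#' @param scores A [score_guides()] result.
#' @param manifest Guide manifest providing the `category` of each guide.
#' @return A `screen_qc` tibble: one row per (cell_line, editor) with
#'   `median_z_*` columns and `control_auroc`.
#' @export
control_qc <- function(scores, manifest) {
  joined <- as_tibble(scores) |>
    inner_join(manifest[, c("guide_id", "category")], by = "guide_id") |>
    filter(pass_filter)
  qc <- joined |>
    group_by(cell_line, editor) |>
    group_modify(function(df, key) {
      for (cat in c("essential_stop_control", "nonessential_stop_control")) {
        if (!any(df$category == cat)) {
          abort(sprintf("screen %s/%s has no scored guides in category '%s'",
                        key$cell_line, key$editor, cat))
        }
      }
      ess <- df$z[df$category == "essential_stop_control"]
      ness <- df$z[df$category == "nonessential_stop_control"]
      tibble(
        n_scored = nrow(df),
        median_z_targeting = median(df$z[df$category == "targeting"]),
        median_z_essential_stop = median(ess),
        median_z_nonessential_stop = median(ness),
        median_z_non_targeting = median(df$z[df$category == "non_targeting"]),
        median_z_intergenic = median(df$z[df$category == "intergenic"]),
        control_auroc = auroc_lower(ess, ness)
      )
    }) |>
    ungroup()
  structure(qc, class = c("screen_qc", class(qc)))
}
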