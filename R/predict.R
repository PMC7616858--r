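# Editor-outcome prediction. "Combined" mode converts every editable base in
# the window simultaneously (the bystander-inclusive annotation used for
# scoring); "individual" mode emits one prediction per editable base.

CONSEQUENCE_LEVELS <- c("splice_donor", "splice_acceptor", "nonsense",
                        "start_loss", "stop_loss", "missense", "synonymous",
                        "promoter", "intronic", "no_edit")
PROTEIN_CONSEQUENCES <- c("synonymous", "missense", "nonsense", "start_loss",
                          "stop_loss")

#' Predict editor-specific edits for a guide library
#'
#' For each targeting guide, enumerates the editable bases (the editor's
#' substrate base on the protospacer strand) inside the editing window and
#' maps them to contig coordinates. Non-targeting, intergenic and stop-control
#' guides yield `no_edit` predictions. Consequences are left unclassified;
#' see [classify_consequence()] or the one-step [annotate_guides()].
#'
#' @param guides Guide tibble (see [scan_guides()]).
#' @param editor An [editor_spec()] or `"ABE"`/`"CBE"`.
#' @param mode `"combined"` (all window bases converted at once; one row per
#'   guide) or `"individual"` (one row per editable base).
#' @param model Optional [gene_model()]; when given, targeting guides are
#'   checked against the reference and a mismatch is an error naming the
#'   first mismatching protospacer position.
#' @return Tibble with one prediction per row: `guide_id`, `category`,
#'   `editor`, `mode`, `edit_index`, `n_edits`, and a list-column `edits`
#'   of per-base tibbles (`protospacer_pos`, `contig_pos`, `ref_base`,
#'   `alt_base` on the protospacer strand, `alt_contig` on the contig plus
#'   strand). Consequence columns are `NA` until classified.
#' @export
predict_edits <- function(guides, editor, mode = c("combined", "individual"),
                          model = NULL) {
  mode <- arg_match(mode)
  editor <- as_editor_spec(editor)
  guides <- as_tibble(guides)
  if (any(nchar(guides$protospacer) != 20)) {
    abort("all protospacers must be 20 nt")
  }
  if (!is.null(model)) {
    mm <- reference_mismatches(guides, model)
    if (nrow(mm) > 0) {
      abort(sprintf(
        "guide %s does not match the reference (first mismatch at protospacer position %d)",
        mm$guide_id[1], mm$first_mismatch_pos[1]
      ))
    }
  }

  targeting <- guides$category == "targeting" & !is.na(guides$contig_start)
  win <- seq.int(editor$window[1], editor$window[2])

  # long table of editable window bases across all targeting guides
  long <- list()
  for (p in win) {
    base <- substr(guides$protospacer, p, p)
    hit <- which(targeting & base == editor$from)
    if (length(hit)) {
      long[[length(long) + 1]] <- tibble(
        g = hit,
        protospacer_pos = p,
        contig_pos = protospacer_to_contig(guides$contig_start[hit],
                                           guides$strand[hit], p),
        ref_base = editor$from,
        alt_base = editor$to,
        alt_contig = ifelse(guides$strand[hit] == "+",
                            editor$to, comp_base(editor$to))
      )
    }
  }
  long <- if (length(long)) arrange(bind_rows(long), g, protospacer_pos) else
    tibble(g = integer(), protospacer_pos = integer(), contig_pos = integer(),
           ref_base = character(), alt_base = character(),
           alt_contig = character())

  empty_edits <- long[0, -1]
  if (mode == "combined") {
    edits_by_guide <- split(long[, -1], factor(long$g, levels = seq_len(nrow(guides))))
    preds <- tibble(
      guide_id = guides$guide_id,
      category = guides$category,
      editor = editor$name,
      mode = mode,
      edit_index = NA_integer_,
      n_edits = unname(vapply(edits_by_guide, nrow, integer(1))),
      edits = unname(edits_by_guide)
    )
  } else {
    with_edits <- tibble(
      guide_id = guides$guide_id[long$g],
      category = guides$category[long$g],
      editor = editor$name,
      mode = mode,
      edit_index = stats::ave(long$g, long$g, FUN = seq_along),
      n_edits = 1L,
      edits = lapply(seq_len(nrow(long)), function(i) long[i, -1])
    )
    no_edit_guides <- setdiff(seq_len(nrow(guides)), unique(long$g))
    without <- tibble(
      guide_id = guides$guide_id[no_edit_guides],
      category = guides$category[no_edit_guides],
      editor = editor$name,
      mode = mode,
      edit_index = NA_integer_,
      n_edits = 0L,
      edits = rep(list(empty_edits), length(no_edit_guides))
    )
    preds <- bind_rows(with_edits, without)
    preds <- preds[order(match(preds$guide_id, guides$guide_id),
                         preds$edit_index), ]
  }

  preds$consequence <- NA_character_
  preds$protein_changes <- rep(list(NULL), nrow(preds))
  preds$installs_proline <- NA
  preds$splice_residue <- NA_integer_
  preds
}

#' Classify the consequence of predicted edits
#'
#' Applies each prediction's edits to the coding-strand sequence,
#' re-translates the affected codons and assigns the single highest-priority
#' consequence: splice (donor/acceptor) > nonsense > start_loss > stop_loss >
#' missense > synonymous > promoter > intronic > no_edit. Splice consequences
#' are limited to the canonical 2-nt GT/AG intron cores. Edits falling
#' entirely outside the gene footprint give `no_edit` with a warning.
#'
#' @param predictions Output of [predict_edits()].
#' @param model A [gene_model()].
#' @return The predictions tibble with `consequence`, `protein_changes`
#'   (list-column of tibbles `residue`, `ref_aa`, `alt_aa`; the stop codon is
#'   residue `nchar(protein) + 1` with `ref_aa = "*"`), `installs_proline`
#'   and `splice_residue` (nearest exonic residue flanking a disrupted
#'   intron boundary) filled in.
#' @export
classify_consequence <- function(predictions, model) {
  idx <- model_index(model)
  L <- nchar(model$contig_seq)
  n_codons <- model$n_codons
  preds <- as_tibble(predictions)
  n <- nrow(preds)

  # explode the edits list-column
  n_edits <- vapply(preds$edits, nrow, integer(1))
  row_id <- rep.int(seq_len(n), n_edits)
  long <- bind_rows(preds$edits)
  long$row <- row_id

  out_conseq <- rep("no_edit", n)
  out_changes <- rep(list(tibble(residue = integer(), ref_aa = character(),
                                 alt_aa = character())), n)
  out_proline <- rep(FALSE, n)
  out_splice_res <- rep(NA_integer_, n)

  outside_warn <- character()

  if (nrow(long) > 0) {
    pos <- long$contig_pos
    in_contig <- pos >= 1 & pos <= L
    splice_kind <- ifelse(in_contig, idx$splice_kind[pmax(pos, 1L)], NA)
    splice_intron <- ifelse(in_contig, idx$splice_intron[pmax(pos, 1L)], NA)
    cds_off <- ifelse(in_contig, idx$cds_off[pmax(pos, 1L)], NA)
    in_promoter <- in_contig & idx$promoter_mask[pmax(pos, 1L)]
    in_intron <- in_contig & !is.na(idx$intron_id[pmax(pos, 1L)])
    in_footprint <- in_promoter | in_intron | (in_contig & idx$exon_mask[pmax(pos, 1L)])

    # --- codon re-translation for CDS edits ---
    is_cds <- !is.na(cds_off)
    codon_tab <- NULL
    if (any(is_cds)) {
      ce <- tibble(
        row = long$row[is_cds],
        off = cds_off[is_cds],
        alt_coding = if (model$strand == "+") long$alt_contig[is_cds] else
          comp_base(long$alt_contig[is_cds])
      )
      ce$codon_idx <- (ce$off - 1L) %/% 3L + 1L
      ce$in_codon <- (ce$off - 1L) %% 3L + 1L
      key <- paste(ce$row, ce$codon_idx)
      ukey <- unique(key)
      slot <- match(key, ukey)
      first <- match(ukey, key)
      u_row <- ce$row[first]
      u_ci <- ce$codon_idx[first]
      old <- substring(idx$cds_seq, 3L * u_ci - 2L, 3L * u_ci)
      chars <- matrix(unlist(strsplit(old, ""), use.names = FALSE), nrow = 3)
      chars[cbind(ce$in_codon, slot)] <- ce$alt_coding
      new <- paste0(chars[1, ], chars[2, ], chars[3, ])
      old_aa <- unname(Biostrings::GENETIC_CODE[old])
      new_aa <- unname(Biostrings::GENETIC_CODE[new])
      codon_tab <- tibble(row = u_row, residue = u_ci, ref_aa = old_aa,
                          alt_aa = new_aa, changed = old_aa != new_aa)
    }

    # --- per-prediction classification ---
    agg_flag <- function(mask, rows) {
      v <- rep(FALSE, n)
      if (any(mask)) v[unique(rows[mask])] <- TRUE
      v
    }
    has_donor <- agg_flag(!is.na(splice_kind) & splice_kind == "donor", long$row)
    has_acceptor <- agg_flag(!is.na(splice_kind) & splice_kind == "acceptor", long$row)
    has_promoter <- agg_flag(in_promoter, long$row)
    has_intron <- agg_flag(in_intron, long$row)
    has_edit_in_footprint <- agg_flag(in_footprint, long$row)
    any_edit <- agg_flag(rep(TRUE, nrow(long)), long$row)

    has_nonsense <- has_start_loss <- has_stop_loss <- has_missense <-
      has_cds <- rep(FALSE, n)
    if (!is.null(codon_tab)) {
      ct <- codon_tab
      has_cds[unique(ct$row)] <- TRUE
      is_nonsense <- ct$changed & ct$alt_aa == "*" & ct$ref_aa != "*"
      is_start_loss <- ct$changed & ct$residue == 1L
      is_stop_loss <- ct$changed & ct$residue == n_codons & ct$ref_aa == "*"
      is_missense <- ct$changed & !is_nonsense & !is_start_loss & !is_stop_loss
      has_nonsense[unique(ct$row[is_nonsense])] <- TRUE
      has_start_loss[unique(ct$row[is_start_loss])] <- TRUE
      has_stop_loss[unique(ct$row[is_stop_loss])] <- TRUE
      has_missense[unique(ct$row[is_missense])] <- TRUE
    }

    out_conseq <- dplyr::case_when(
      has_donor ~ "splice_donor",
      has_acceptor ~ "splice_acceptor",
      has_nonsense ~ "nonsense",
      has_start_loss ~ "start_loss",
      has_stop_loss ~ "stop_loss",
      has_missense ~ "missense",
      has_cds ~ "synonymous",
      has_promoter ~ "promoter",
      has_intron ~ "intronic",
      .default = "no_edit"
    )

    # edits present but all outside the gene footprint -> warn
    outside_rows <- any_edit & !has_edit_in_footprint
    if (any(outside_rows)) {
      outside_warn <- unique(preds$guide_id[outside_rows])
    }

    # protein changes
    if (!is.null(codon_tab)) {
      take_changed <- out_conseq[codon_tab$row] %in%
        c("missense", "nonsense", "start_loss", "stop_loss") & codon_tab$changed
      take_syn <- out_conseq[codon_tab$row] == "synonymous"
      take <- take_changed | take_syn
      if (any(take)) {
        sel <- codon_tab[take, c("row", "residue", "ref_aa", "alt_aa")]
        sel <- arrange(sel, row, residue)
        by_row <- split(sel[, c("residue", "ref_aa", "alt_aa")], sel$row)
        out_changes[as.integer(names(by_row))] <- unname(by_row)
      }
      prol <- codon_tab$changed & codon_tab$alt_aa == "P"
      out_proline[unique(codon_tab$row[prol])] <- TRUE
    }

    # splice residue: nearest exonic residue flanking the disrupted boundary
    splice_rows <- which(out_conseq %in% c("splice_donor", "splice_acceptor"))
    if (length(splice_rows)) {
      for (r in splice_rows) {
        sel <- long$row == r & !is.na(splice_kind) &
          splice_kind == ifelse(out_conseq[r] == "splice_donor", "donor", "acceptor")
        intr <- splice_intron[sel][1]
        out_splice_res[r] <- if (out_conseq[r] == "splice_donor")
          idx$donor_res[intr] else idx$acc_res[intr]
      }
    }
  }

  if (length(outside_warn)) {
    warn(sprintf(
      "%d guide(s) have edits only outside the gene footprint (classified no_edit): %s%s",
      length(outside_warn), paste(head(outside_warn, 3), collapse = ", "),
      if (length(outside_warn) > 3) ", ..." else ""
    ))
  }

  preds$consequence <- out_conseq
  preds$protein_changes <- out_changes
  preds$installs_proline <- out_proline
  preds$splice_residue <- out_splice_res
  preds
}

#' Predict and classify in one step
#'
#' Convenience wrapper running [predict_edits()] then
#' [classify_consequence()].
#'
#' @inheritParams predict_edits
#' @inheritParams classify_consequence
#' @return Classified prediction tibble.
#' @export
annotate_guides <- function(guides, model, editor,
                            mode = c("combined", "individual")) {
  classify_consequence(predict_edits(guides, editor, mode, model = model),
                       model)
}

# compact string form "727:C>T;728:C>T" used by the TSV writers
edits_to_string <- function(edits) {
  vapply(edits, function(e) {
    if (nrow(e) == 0) return("")
    paste(sprintf("%d:%s>%s", e$contig_pos, e$ref_base, e$alt_base),
          collapse = ";")
  }, character(1))
}

protein_changes_to_string <- function(changes) {
  vapply(changes, function(pc) {
    if (is.null(pc) || nrow(pc) == 0) return("")
    paste(sprintf("%s%d%s", pc$ref_aa, pc$residue, pc$alt_aa), collapse = ";")
  }, character(1))
}
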