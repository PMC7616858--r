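# Independent brute-force oracles. These deliberately avoid the package's
# incremental code paths: the consequence oracle mutates the whole contig
# string, re-extracts and re-translates the entire CDS and diffs proteins;
# the scoring oracle is a straight-line loop; the enrichment oracle
# enumerates hit placements exhaustively.

# ---- consequence oracle -----------------------------------------------------

oracle_translate <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq)))
}

oracle_consequence <- function(guide, editor, model) {
  pro <- guide$protospacer
  st <- guide$contig_start
  gstrand <- guide$strand
  w <- seq(editor$window[1], editor$window[2])
  bases <- strsplit(pro, "")[[1]]
  edit_p <- w[bases[w] == editor$from]
  empty <- tibble::tibble(residue = integer(), ref_aa = character(),
                          alt_aa = character())
  if (length(edit_p) == 0) {
    return(list(consequence = "no_edit", changes = empty, proline = FALSE))
  }

  contig <- strsplit(model$contig_seq, "")[[1]]
  cpos <- integer(0)
  for (p in edit_p) {
    cp <- if (gstrand == "+") st + p - 1L else st + 20L - p
    alt <- if (gstrand == "+") editor$to else chartr("ACGT", "TGCA", editor$to)
    contig[cp] <- alt
    cpos <- c(cpos, cp)
  }
  edited <- paste(contig, collapse = "")

  # region membership, computed directly from the interval tables
  ex <- model$exons
  in_exon <- vapply(cpos, function(p) any(ex$start <= p & p <= ex$end),
                    logical(1))
  in_promoter <- if (!is.null(model$promoter)) {
    cpos >= model$promoter$start[1] & cpos <= model$promoter$end[1]
  } else rep(FALSE, length(cpos))
  introns <- if (nrow(ex) >= 2) {
    data.frame(start = ex$end[-nrow(ex)] + 1, end = ex$start[-1] - 1)
  } else data.frame(start = integer(), end = integer())
  in_intron <- vapply(cpos, function(p) {
    nrow(introns) > 0 && any(introns$start <= p & p <= introns$end)
  }, logical(1))

  donor_pos <- acceptor_pos <- integer(0)
  if (nrow(introns) > 0) {
    for (i in seq_len(nrow(introns))) {
      s <- introns$start[i]; e <- introns$end[i]
      if (model$strand == "+") {
        donor_pos <- c(donor_pos, s, s + 1L)
        acceptor_pos <- c(acceptor_pos, e - 1L, e)
      } else {
        donor_pos <- c(donor_pos, e, e - 1L)
        acceptor_pos <- c(acceptor_pos, s, s + 1L)
      }
    }
  }

  # whole-CDS re-extraction + re-translation on the edited contig
  get_cds <- function(seq) {
    out <- paste(substring(seq, model$cds$start, model$cds$end), collapse = "")
    if (model$strand == "-") {
      out <- paste(rev(strsplit(chartr("ACGT", "TGCA", out), "")[[1]]),
                   collapse = "")
    }
    out
  }
  aa_old <- oracle_translate(get_cds(model$contig_seq))
  aa_new <- oracle_translate(get_cds(edited))
  n_codons <- nchar(aa_old)
  old_v <- strsplit(aa_old, "")[[1]]
  new_v <- strsplit(aa_new, "")[[1]]
  diff <- which(old_v != new_v)

  # codons touched by CDS edits (independent offset arithmetic)
  cds_positions <- unlist(Map(seq.int, model$cds$start, model$cds$end))
  if (model$strand == "-") cds_positions <- rev(cds_positions)
  touched <- sort(unique(ceiling(match(cpos, cds_positions) / 3)))
  touched <- touched[!is.na(touched)]

  has_splice_donor <- any(cpos %in% donor_pos)
  has_splice_acceptor <- any(cpos %in% acceptor_pos)
  has_nonsense <- any(new_v[diff] == "*" & old_v[diff] != "*")
  has_start_loss <- 1 %in% diff
  has_stop_loss <- any(diff == n_codons & old_v[n_codons] == "*")
  has_missense <- any(old_v[diff] != new_v[diff] & new_v[diff] != "*" &
                        diff != 1 &
                        !(diff == n_codons & old_v[n_codons] == "*"))
  has_cds_edit <- length(touched) > 0

  consequence <-
    if (has_splice_donor) "splice_donor" else
    if (has_splice_acceptor) "splice_acceptor" else
    if (has_nonsense) "nonsense" else
    if (has_start_loss) "start_loss" else
    if (has_stop_loss) "stop_loss" else
    if (has_missense) "missense" else
    if (has_cds_edit) "synonymous" else
    if (any(in_promoter)) "promoter" else
    if (any(in_intron)) "intronic" else "no_edit"

  changes <- empty
  if (consequence %in% c("missense", "nonsense", "start_loss", "stop_loss")) {
    changes <- tibble::tibble(residue = diff, ref_aa = old_v[diff],
                              alt_aa = new_v[diff])
  } else if (consequence == "synonymous") {
    changes <- tibble::tibble(residue = touched, ref_aa = old_v[touched],
                              alt_aa = old_v[touched])
  }
  list(consequence = consequence, changes = changes,
       proline = any(new_v[diff] == "P"))
}

# draw one random model and check up to n_guides random guides under a
# random editor against the oracle; returns a logical vector of agreements
check_random_model_batch <- function(n_guides = 10) {
  m <- random_tiny_model(minus = runif(1) < 0.5)
  g <- scan_guides(m, region = tibble::tibble(
    start = min(m$exons$start, m$promoter$start[1]) - 5,
    end = max(m$exons$end, m$promoter$end[1]) + 5
  ))
  if (nrow(g) == 0) return(logical(0))
  g <- g[sample.int(nrow(g), min(n_guides, nrow(g))), ]
  ed <- editor_spec(sample(c("ABE", "CBE"), 1))
  preds <- suppressWarnings(annotate_guides(g, m, ed))
  vapply(seq_len(nrow(g)), function(i) {
    orc <- oracle_consequence(g[i, ], ed, m)
    pc <- preds$protein_changes[[i]]
    ok_changes <- isTRUE(all.equal(
      as.data.frame(pc[order(pc$residue), ]),
      as.data.frame(orc$changes[order(orc$changes$residue), ]),
      check.attributes = FALSE
    )) || (nrow(pc) == 0 && nrow(orc$changes) == 0)
    identical(preds$consequence[i], orc$consequence) && ok_changes &&
      identical(preds$installs_proline[i], orc$proline)
  }, logical(1))
}

# ---- scoring oracle ---------------------------------------------------------

# straight-line recomputation of the RPM / L2FC / z chain for one screen
# with counts as a plain matrix (guides x samples)
oracle_score_screen <- function(count_mat, timepoints, pseudocount = 1,
                                min_t0 = 100, center_z = TRUE) {
  n <- nrow(count_mat)
  rpm <- count_mat
  for (j in seq_len(ncol(count_mat))) {
    x <- count_mat[, j] + pseudocount
    rpm[, j] <- x / sum(x) * 1e6
  }
  t0_cols <- which(timepoints == "T0")
  end_cols <- which(timepoints == "Tend")
  mean_rpm_t0 <- rowMeans(rpm[, t0_cols, drop = FALSE])
  mean_rpm_end <- rowMeans(rpm[, end_cols, drop = FALSE])
  mean_raw_t0 <- rowMeans(count_mat[, t0_cols, drop = FALSE])
  pass <- mean_raw_t0 >= min_t0
  l2fc <- rep(NA_real_, n)
  l2fc[pass] <- log2(mean_rpm_end[pass] / mean_rpm_t0[pass])
  mu <- if (center_z) mean(l2fc[pass]) else 0
  sdv <- sd(l2fc[pass])
  z <- (l2fc - mu) / sdv
  list(mean_rpm_t0 = mean_rpm_t0, mean_rpm_end = mean_rpm_end,
       pass = pass, l2fc = l2fc, z = z)
}

# random one-screen counts fixture: n guides, 2 T0 + 2 Tend samples
random_screen_fixture <- function(n = 50) {
  counts <- tibble::tibble(
    guide_id = sprintf("g%03d", seq_len(n)),
    S1 = rnbinom(n, mu = 300, size = 5), S2 = rnbinom(n, mu = 300, size = 5),
    S3 = rnbinom(n, mu = 300, size = 5), S4 = rnbinom(n, mu = 300, size = 5)
  )
  samples <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4"), cell_line = "cl", editor = "CBE",
    timepoint = c("T0", "T0", "Tend", "Tend"), replicate = c(1L, 2L, 1L, 2L)
  )
  list(counts = counts, samples = samples)
}

# ---- enrichment oracle ------------------------------------------------------

# exhaustive enumeration: universe of n residues, H hits placed uniformly,
# domain = first k residues; P(overlap >= observed hits_in)
enum_hyper_p <- function(n_universe, n_hits, covered_in, hits_in) {
  if (n_hits == 0) return(as.numeric(hits_in <= 0))
  sets <- utils::combn(n_universe, n_hits)
  inside <- colSums(sets <= covered_in)
  mean(inside >= hits_in)
}

# naive pairwise AUROC: P(x < y) + 0.5 P(x = y)
naive_auroc_lower <- function(x, y) {
  o <- outer(x, y, "<") + 0.5 * outer(x, y, "==")
  mean(o)
}
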