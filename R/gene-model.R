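#' Construct and validate a gene model
#'
#' A gene model bundles a reference contig with the exon/CDS structure of a
#' single protein-coding transcript, plus an optional promoter interval, and
#' derives the protein sequence. Analysis assumes a wild-type genome: the
#' contig sequence is taken as the baseline for every sample, and no
#' sample-specific variants are applied.
#'
#' All coordinates are 1-based inclusive on the contig. For minus-strand genes
#' every "coding strand" computation operates on the reverse complement; exon
#' and CDS intervals are still stored in contig order.
#'
#' @param gene_id,contig_id Identifiers.
#' @param contig_seq Contig nucleotide string (A/C/G/T/N).
#' @param strand `"+"` or `"-"`: strand of the gene on the contig.
#' @param exons,cds Data frames with `start`, `end` columns (1-based
#'   inclusive), sorted, non-overlapping; every CDS interval must lie inside
#'   an exon.
#' @param promoter Optional length-2 numeric `c(start, end)` or one-row data
#'   frame: promoter interval upstream of the first exon (coding-strand
#'   upstream).
#' @param splice How to treat non-canonical intron dinucleotides (canonical:
#'   introns begin `GT` and end `AG` on the coding strand): `"error"` for
#'   synthetic fixtures, `"warn"` for real annotation.
#' @return An object of class `gene_model`: a list with the validated fields
#'   plus the derived `protein` (trailing stop trimmed) and `n_codons`.
#' @seealso [load_gene_model()], [splice_sites()], [extract_cds()]
#' @export
gene_model <- function(gene_id, contig_id, contig_seq, strand = c("+", "-"),
                       exons, cds, promoter = NULL,
                       splice = c("error", "warn")) {
  strand <- arg_match(strand)
  splice <- arg_match(splice)
  contig_seq <- toupper(contig_seq)
  check_dna(contig_seq, "contig")
  exons <- normalize_intervals(exons, "exons", nchar(contig_seq))
  cds <- normalize_intervals(cds, "cds", nchar(contig_seq))
  if (!is.null(promoter)) {
    if (is.numeric(promoter) && length(promoter) == 2) {
      promoter <- tibble(start = promoter[1], end = promoter[2])
    }
    promoter <- normalize_intervals(promoter, "promoter", nchar(contig_seq))
    stopifnot(nrow(promoter) == 1)
  }

  # each cds interval contained in an exon
  for (i in seq_len(nrow(cds))) {
    inside <- any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    if (!inside) {
      abort(sprintf("CDS interval [%d,%d] not contained in any exon",
                    cds$start[i], cds$end[i]))
    }
  }

  cds_len <- sum(cds$end - cds$start + 1)
  if (cds_len %% 3 != 0) {
    abort(sprintf(
      "CDS length %d not divisible by 3 (last interval [%d,%d])",
      cds_len, cds$start[nrow(cds)], cds$end[nrow(cds)]
    ))
  }

  model <- structure(
    list(gene_id = gene_id, contig_id = contig_id, contig_seq = contig_seq,
         strand = strand, exons = exons, cds = cds, promoter = promoter,
         protein = NULL, n_codons = cds_len / 3L),
    class = "gene_model"
  )

  aa <- translate_dna(extract_cds(model))
  internal_stop <- regexpr("\\*", substr(aa, 1, nchar(aa) - 1))
  if (internal_stop > 0) {
    abort(sprintf("internal stop codon at codon %d", as.integer(internal_stop)))
  }
  if (substr(aa, nchar(aa), nchar(aa)) != "*") {
    abort("CDS does not end at a stop codon")
  }
  model$protein <- substr(aa, 1, nchar(aa) - 1)

  check_splice_dinucleotides(model, action = splice)
  model
}

normalize_intervals <- function(x, what, contig_len) {
  x <- as_tibble(x)
  if (!all(c("start", "end") %in% names(x))) {
    abort(sprintf("%s must have 'start' and 'end' columns", what))
  }
  x <- tibble(start = as.integer(x$start), end = as.integer(x$end))
  if (nrow(x) == 0) abort(sprintf("%s is empty", what))
  if (any(x$start > x$end)) abort(sprintf("%s has start > end", what))
  if (any(x$start < 1 | x$end > contig_len)) {
    abort(sprintf("%s extends outside the contig", what))
  }
  x <- arrange(x, start)
  if (nrow(x) > 1 && any(x$start[-1] <= x$end[-nrow(x)])) {
    abort(sprintf("%s intervals overlap or are unsorted", what))
  }
  x
}

# introns = gaps between consecutive exons, contig order
intron_table <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2) {
    return(tibble(intron = integer(), start = integer(), end = integer()))
  }
  tibble(
    intron = seq_len(nrow(ex) - 1),
    start = ex$end[-nrow(ex)] + 1L,
    end = ex$start[-1] - 1L
  )
}

check_splice_dinucleotides <- function(model, action = c("error", "warn")) {
  action <- arg_match(action)
  ss <- splice_sites(model)
  if (nrow(ss) == 0) return(invisible(TRUE))
  expected <- ifelse(ss$kind == "donor", c("G", "T")[ss$offset],
                     c("A", "G")[ss$offset])
  bad <- ss$base != expected
  if (any(bad)) {
    msg <- sprintf(
      "non-canonical splice dinucleotide(s) at contig position(s) %s",
      paste(ss$contig_pos[bad], collapse = ", ")
    )
    if (action == "error") abort(msg) else warn(msg)
  }
  invisible(TRUE)
}

#' Canonical splice-site positions of a gene model
#'
#' Returns the 2-nt donor (GT) and acceptor (AG) core positions of every
#' intron, oriented on the coding strand: for minus-strand genes the donor
#' lies at the contig-rightmost end of the intron. `base` is the coding-strand
#' base at each position.
#'
#' @param model A [gene_model()].
#' @return A tibble with columns `intron`, `kind` (`donor`/`acceptor`),
#'   `offset` (1 or 2 within the dinucleotide, coding order), `contig_pos`,
#'   `base`. Empty for single-exon genes.
#' @export
splice_sites <- function(model) {
  introns <- intron_table(model)
  if (nrow(introns) == 0) {
    return(tibble(intron = integer(), kind = character(), offset = integer(),
                  contig_pos = integer(), base = character()))
  }
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    s <- introns$start[i]; e <- introns$end[i]
    if (model$strand == "+") {
      tibble(
        intron = i,
        kind = c("donor", "donor", "acceptor", "acceptor"),
        offset = c(1L, 2L, 1L, 2L),
        contig_pos = c(s, s + 1L, e - 1L, e)
      )
    } else {
      # coding strand reads right-to-left: donor core at contig-right end
      tibble(
        intron = i,
        kind = c("donor", "donor", "acceptor", "acceptor"),
        offset = c(1L, 2L, 1L, 2L),
        contig_pos = c(e, e - 1L, s + 1L, s)
      )
    }
  })
  out <- bind_rows(rows)
  base_on_contig <- substring(model$contig_seq, out$contig_pos, out$contig_pos)
  out$base <- if (model$strand == "+") base_on_contig else comp_base(base_on_contig)
  out
}

#' Extract the coding sequence of a gene model
#'
#' Concatenates the CDS intervals in coding order; for minus-strand genes the
#' result is the reverse complement of the contig-order concatenation.
#'
#' @param model A [gene_model()].
#' @param contig_seq Optional replacement contig sequence (same length);
#'   used when evaluating edited genomes.
#' @return Nucleotide string.
#' @export
extract_cds <- function(model, contig_seq = NULL) {
  seq <- contig_seq %||% model$contig_seq
  pieces <- substring(seq, model$cds$start, model$cds$end)
  out <- paste(pieces, collapse = "")
  if (model$strand == "-") out <- revcomp(out) else out
}

# Map every contig position to its CDS offset (1..L in coding order), NA
# elsewhere. Also classify positions: promoter / intron / splice cores.
model_index <- function(model) {
  L <- nchar(model$contig_seq)
  cds_off <- rep(NA_integer_, L)
  pos <- unlist(Map(seq.int, model$cds$start, model$cds$end), use.names = FALSE)
  cds_off[pos] <- if (model$strand == "+") seq_along(pos) else rev(seq_along(pos))

  intron_id <- rep(NA_integer_, L)
  introns <- intron_table(model)
  if (nrow(introns) > 0) {
    ipos <- unlist(Map(seq.int, introns$start, introns$end), use.names = FALSE)
    intron_id[ipos] <- rep.int(introns$intron, introns$end - introns$start + 1L)
  }

  splice_kind <- rep(NA_character_, L)
  splice_intron <- rep(NA_integer_, L)
  ss <- splice_sites(model)
  if (nrow(ss) > 0) {
    splice_kind[ss$contig_pos] <- ss$kind
    splice_intron[ss$contig_pos] <- ss$intron
  }

  promoter_mask <- rep(FALSE, L)
  if (!is.null(model$promoter)) {
    promoter_mask[seq.int(model$promoter$start[1], model$promoter$end[1])] <- TRUE
  }

  exon_mask <- rep(FALSE, L)
  epos <- unlist(Map(seq.int, model$exons$start, model$exons$end), use.names = FALSE)
  exon_mask[epos] <- TRUE

  # flanking exonic residue per intron boundary (for splice-guide display)
  donor_res <- acc_res <- rep(NA_integer_, max(1L, nrow(introns)))
  if (nrow(introns) > 0) {
    for (i in seq_len(nrow(introns))) {
      left_exon_end <- introns$start[i] - 1L    # exon base left of intron
      right_exon_start <- introns$end[i] + 1L   # exon base right of intron
      off_left <- cds_off[left_exon_end]
      off_right <- cds_off[right_exon_start]
      if (model$strand == "+") {
        donor_res[i] <- if (!is.na(off_left)) ceiling(off_left / 3) else NA_integer_
        acc_res[i] <- if (!is.na(off_right)) ceiling(off_right / 3) else NA_integer_
      } else {
        donor_res[i] <- if (!is.na(off_right)) ceiling(off_right / 3) else NA_integer_
        acc_res[i] <- if (!is.na(off_left)) ceiling(off_left / 3) else NA_integer_
      }
    }
  }

  list(cds_off = cds_off, intron_id = intron_id, splice_kind = splice_kind,
       splice_intron = splice_intron, promoter_mask = promoter_mask,
       exon_mask = exon_mask, donor_res = donor_res, acc_res = acc_res,
       cds_seq = extract_cds(model))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s on %s (%s strand)\n  contig %d nt, %d exon(s), CDS %d nt, protein %d aa\n",
    x$gene_id, x$contig_id, x$strand, nchar(x$contig_seq), nrow(x$exons),
    3L * x$n_codons, nchar(x$protein)
  ))
  invisible(x)
}

#' Reverse-complement an entire gene model
#'
#' Flips the contig and every annotated interval, switching the gene strand.
#' The protein and all consequence calls are invariant under this
#' transformation, which the test-suite exploits as a strand-symmetry check.
#'
#' @param model A [gene_model()].
#' @return A [gene_model()] on the opposite strand of the flipped contig.
#' @export
revcomp_gene_model <- function(model) {
  L <- nchar(model$contig_seq)
  flip <- function(iv) {
    tibble(start = L - iv$end + 1L, end = L - iv$start + 1L) |> arrange(start)
  }
  gene_model(
    gene_id = model$gene_id,
    contig_id = model$contig_id,
    contig_seq = revcomp(model$contig_seq),
    strand = if (model$strand == "+") "-" else "+",
    exons = flip(model$exons),
    cds = flip(model$cds),
    promoter = if (is.null(model$promoter)) NULL else flip(model$promoter),
    splice = "error"
  )
}
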