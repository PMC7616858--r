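# GFF3 + FASTA round-trip for gene models. File parsing is delegated to
# Biostrings (FASTA) and rtracklayer (GFF3); this layer only assembles the
# validated gene_model from the imported features.

#' Load a gene model from FASTA + GFF3
#'
#' Reads the reference contig from `fasta_path` and the gene's exon/CDS
#' (and optional promoter) features from `gff_path`. GFF3 coordinates are
#' 1-based inclusive and are used as-is.
#'
#' @param fasta_path Path to a FASTA file containing the contig.
#' @param gff_path Path to a GFF3 file with `exon` and `CDS` features whose
#'   `Parent`/`ID` attributes link them to `gene_id`.
#' @param gene_id Identifier of the gene to load.
#' @param splice Passed to [gene_model()]: `"warn"` (default for real
#'   annotation) or `"error"` for non-canonical splice dinucleotides.
#' @return A validated [gene_model()].
#' @export
load_gene_model <- function(fasta_path, gff_path, gene_id,
                            splice = c("warn", "error")) {
  splice <- arg_match(splice)
  gr <- rtracklayer::import(gff_path)
  ids <- as.character(S4Vectors::mcols(gr)$ID)
  parents <- vapply(
    as.list(S4Vectors::mcols(gr)$Parent %||% ids),
    function(p) if (length(p)) as.character(p)[1] else NA_character_,
    character(1)
  )
  gene_rows <- which(!is.na(ids) & ids == gene_id)
  if (length(gene_rows) == 0) {
    abort(sprintf("gene '%s' not found in %s", gene_id, gff_path))
  }
  # transcripts of the gene, or the gene itself if features attach directly
  tx_ids <- ids[!is.na(parents) & parents == gene_id &
                  !(as.character(gr$type) %in% c("exon", "CDS", "promoter"))]
  owner_ids <- unique(c(gene_id, tx_ids[!is.na(tx_ids)]))
  child <- !is.na(parents) & parents %in% owner_ids

  take <- function(type) {
    sel <- gr[child & as.character(gr$type) == type]
    if (length(sel) == 0) return(NULL)
    tibble(start = BiocGenerics::start(sel), end = BiocGenerics::end(sel))
  }
  exons <- take("exon")
  cds <- take("CDS")
  if (is.null(exons) || is.null(cds)) {
    abort(sprintf("gene '%s' must have exon and CDS features", gene_id))
  }
  promoter <- take("promoter")

  contig_id <- as.character(GenomicRanges::seqnames(gr[gene_rows[1]]))
  strand <- as.character(BiocGenerics::strand(gr[gene_rows[1]]))
  if (!strand %in% c("+", "-")) strand <- "+"

  fa <- Biostrings::readDNAStringSet(fasta_path)
  names(fa) <- sub("\\s.*$", "", names(fa))
  if (!contig_id %in% names(fa)) {
    abort(sprintf("contig '%s' not found in %s", contig_id, fasta_path))
  }

  gene_model(
    gene_id = gene_id, contig_id = contig_id,
    contig_seq = as.character(fa[[contig_id]]),
    strand = strand, exons = exons, cds = cds, promoter = promoter,
    splice = splice
  )
}

#' Write a gene model to FASTA + GFF3
#'
#' Inverse of [load_gene_model()]: reloading the written pair yields
#' identical intervals and protein.
#'
#' @param model A [gene_model()].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_gene_model <- function(model, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(setNames(model$contig_seq, model$contig_id))
  Biostrings::writeXStringSet(seqs, fasta_path)

  tx_id <- paste0(model$gene_id, ".t1")
  span <- range(c(model$exons$start, model$exons$end,
                  if (!is.null(model$promoter)) c(model$promoter$start, model$promoter$end)))
  mk <- function(type, start, end, id = NA, parent = NA) {
    n <- length(start)
    parent <- rep_len(parent, n)
    plist <- lapply(parent, function(p) if (is.na(p)) character() else p)
    GenomicRanges::GRanges(
      seqnames = model$contig_id,
      ranges = IRanges::IRanges(start = start, end = end),
      strand = model$strand,
      type = type,
      ID = rep_len(if (is.na(id[1])) NA_character_ else id, n),
      Parent = methods::as(plist, "CharacterList"),
      phase = NA_integer_
    )
  }
  rows <- list(
    mk("gene", span[1], span[2], id = model$gene_id),
    mk("mRNA", min(model$exons$start), max(model$exons$end),
       id = tx_id, parent = model$gene_id),
    mk("exon", model$exons$start, model$exons$end,
       parent = rep(tx_id, nrow(model$exons))),
    mk("CDS", model$cds$start, model$cds$end,
       parent = rep(tx_id, nrow(model$cds)))
  )
  # CDS phase: codon offset at the start of each interval, in coding order
  lens <- model$cds$end - model$cds$start + 1L
  coding_order <- if (model$strand == "+") seq_along(lens) else rev(seq_along(lens))
  before <- cumsum(c(0L, lens[coding_order]))[seq_along(lens)]
  phase <- integer(length(lens))
  phase[coding_order] <- (3L - before %% 3L) %% 3L
  rows[[4]]$phase <- phase
  if (!is.null(model$promoter)) {
    rows <- c(rows, list(mk("promoter", model$promoter$start,
                            model$promoter$end, parent = model$gene_id)))
  }
  gr <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(list(fasta = fasta_path, gff = gff_path))
}
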