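# Small deterministic gene-model fixtures built in code.

flank20 <- "ACCTGAAGGACCTTGGACCA"  # no stop-free constraints needed in flanks

# single-exon toy gene: CDS ATG GCA TGT TAA -> protein "MAC"
toy_single_exon <- function() {
  cds <- "ATGGCATGTTAA"
  contig <- paste0(flank20, cds, flank20)
  gene_model(
    gene_id = "toy1", contig_id = "chrT", contig_seq = contig, strand = "+",
    exons = tibble::tibble(start = 21, end = 32),
    cds = tibble::tibble(start = 21, end = 32)
  )
}

# two-exon toy gene with a 10-nt canonical intron (GTAAG...TTAG)
# exon1 ATGGCA [21,26], intron GTAAGTTTAG [27,36], exon2 TGTTAA [37,42]
toy_two_exon <- function() {
  contig <- paste0(flank20, "ATGGCA", "GTAAGTTTAG", "TGTTAA", flank20)
  gene_model(
    gene_id = "toy2", contig_id = "chrT", contig_seq = contig, strand = "+",
    exons = tibble::tibble(start = c(21, 37), end = c(26, 42)),
    cds = tibble::tibble(start = c(21, 37), end = c(26, 42))
  )
}

# random tiny gene for oracle sweeps: 1-2 exons, short CDS, optional
# promoter; optionally flipped to the minus strand. Uses the session RNG.
random_tiny_model <- function(minus = FALSE) {
  n_codons <- sample(8:14, 1)
  cds <- bescan:::random_orf(n_codons)
  n_exons <- sample(1:2, 1)
  flank <- bescan:::random_dna(25)
  if (n_exons == 1) {
    contig <- paste0(flank, cds, bescan:::random_dna(25))
    exons <- tibble::tibble(start = 26, end = 25 + nchar(cds))
  } else {
    cut <- sample(2:(nchar(cds) - 2), 1)
    intron <- paste0("GT", bescan:::random_dna(sample(8:20, 1)), "AG")
    contig <- paste0(flank, substr(cds, 1, cut), intron,
                     substr(cds, cut + 1, nchar(cds)), bescan:::random_dna(25))
    e1 <- c(26, 25 + cut)
    e2 <- c(e1[2] + nchar(intron) + 1,
            e1[2] + nchar(intron) + nchar(cds) - cut)
    exons <- tibble::tibble(start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))
  }
  promoter <- c(6, 25)
  m <- gene_model(gene_id = "rnd", contig_id = "chrR", contig_seq = contig,
                  strand = "+", exons = exons, cds = exons,
                  promoter = promoter)
  if (minus) revcomp_gene_model(m) else m
}

# manifest row constructor for hand-built guides
guide_row <- function(guide_id, protospacer, contig_start, strand,
                      pam = "AGG", category = "targeting") {
  tibble::tibble(guide_id = guide_id, protospacer = protospacer, pam = pam,
                 contig_start = as.integer(contig_start), strand = strand,
                 category = category)
}

# hand-built classified-prediction row (for residue-map tests)
prediction_row <- function(guide_id, editor, consequence, residues = integer(),
                           ref_aa = NULL, alt_aa = NULL,
                           splice_residue = NA_integer_) {
  pc <- if (length(residues)) {
    tibble::tibble(residue = residues,
                   ref_aa = ref_aa %||% rep("A", length(residues)),
                   alt_aa = alt_aa %||% rep("V", length(residues)))
  } else {
    tibble::tibble(residue = integer(), ref_aa = character(),
                   alt_aa = character())
  }
  tibble::tibble(
    guide_id = guide_id, category = "targeting", editor = editor,
    mode = "combined", edit_index = NA_integer_,
    n_edits = length(residues), edits = list(tibble::tibble()),
    consequence = consequence, protein_changes = list(pc),
    installs_proline = FALSE, splice_residue = splice_residue
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
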