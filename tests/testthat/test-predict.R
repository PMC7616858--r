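test_that("window enumeration matches hand-derived edits", {
  # protospacer positions 4-8 read A,C,C,T,G
  g <- guide_row("g1", "GGGACCTGGGGGGGGGGGGG", 1, "+")

  cbe <- predict_edits(g, "CBE")
  expect_equal(cbe$n_edits, 2L)
  expect_equal(cbe$edits[[1]]$protospacer_pos, c(5L, 6L))
  expect_equal(cbe$edits[[1]]$contig_pos, c(5L, 6L))
  expect_equal(unique(cbe$edits[[1]]$ref_base), "C")
  expect_equal(unique(cbe$edits[[1]]$alt_base), "T")

  abe <- predict_edits(g, "ABE")
  expect_equal(abe$edits[[1]]$protospacer_pos, 4L)
  expect_equal(abe$edits[[1]]$alt_base, "G")

  # no editable base in window
  g2 <- guide_row("g2", "GGGGGTTGGGGGGGGGGGGG", 1, "+")
  expect_equal(predict_edits(g2, "CBE")$n_edits, 0L)
})

test_that("individual mode emits one prediction per editable base", {
  g <- guide_row("g1", "GGGACCTGGGGGGGGGGGGG", 1, "+")
  ind <- predict_edits(g, "CBE", mode = "individual")
  expect_equal(nrow(ind), 2)
  expect_equal(ind$edit_index, c(1L, 2L))
  expect_true(all(ind$n_edits == 1L))
  comb <- predict_edits(g, "CBE", mode = "combined")
  expect_equal(dplyr::bind_rows(ind$edits), comb$edits[[1]])
})

test_that("minus-strand edits map to complementary contig bases", {
  # guide at contig [4, 23] on minus strand; protospacer pos p -> contig 24 - p
  pro <- paste0("GGGACC", strrep("G", 14))
  contig <- paste0("CCA", revcomp(pro), "AAAA")
  g <- guide_row("gm", pro, 4, "-")
  cbe <- predict_edits(g, "CBE")
  e <- cbe$edits[[1]]
  expect_equal(e$protospacer_pos, c(5L, 6L))
  expect_equal(e$contig_pos, c(19L, 18L))
  expect_equal(unique(e$alt_contig), "A")  # C>T on minus = G>A on contig
  expect_equal(substring(contig, e$contig_pos, e$contig_pos), c("G", "G"))
})

test_that("reference mismatches are an error naming the first bad position", {
  m <- toy_single_exon()
  g <- scan_guides(m)[1, ]
  orig <- substr(g$protospacer, 3, 3)
  substr(g$protospacer, 3, 3) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  expect_error(predict_edits(g, "CBE", model = m),
               "position 3")
})

mk_pred <- function(edits, guide_id = "h", editor = "CBE") {
  tibble::tibble(
    guide_id = guide_id, category = "targeting", editor = editor,
    mode = "combined", edit_index = NA_integer_, n_edits = nrow(edits),
    edits = list(edits), consequence = NA_character_,
    protein_changes = list(NULL), installs_proline = NA,
    splice_residue = NA_integer_
  )
}

edit_at <- function(contig_pos, alt_contig, protospacer_pos = 5L) {
  tibble::tibble(protospacer_pos = protospacer_pos, contig_pos = contig_pos,
                 ref_base = "C", alt_base = "T", alt_contig = alt_contig)
}

test_that("codon re-translation assigns missense/nonsense/start/stop classes", {
  m <- toy_single_exon()  # CDS ATG GCA TGT TAA at 21..32

  # GCA -> GTA at codon position 2: missense A2V
  p <- classify_consequence(mk_pred(edit_at(25, "T")), m)
  expect_equal(p$consequence, "missense")
  expect_equal(p$protein_changes[[1]],
               tibble::tibble(residue = 2L, ref_aa = "A", alt_aa = "V"))
  expect_false(p$installs_proline)

  # GCA -> CCA: installs proline
  p <- classify_consequence(mk_pred(edit_at(24, "C")), m)
  expect_equal(p$consequence, "missense")
  expect_true(p$installs_proline)

  # ATG -> GTG: start loss
  p <- classify_consequence(mk_pred(edit_at(21, "G")), m)
  expect_equal(p$consequence, "start_loss")

  # terminal TAA -> CAA: stop loss recorded at the stop-codon index
  p <- classify_consequence(mk_pred(edit_at(30, "C")), m)
  expect_equal(p$consequence, "stop_loss")
  expect_equal(p$protein_changes[[1]]$ref_aa, "*")
  expect_equal(p$protein_changes[[1]]$residue, 4L)

  # CAA -> TAA: nonsense
  contig <- paste0(flank20, "ATGCAATGTTAA", flank20)
  m2 <- gene_model("g", "c", contig, "+",
                   exons = tibble::tibble(start = 21, end = 32),
                   cds = tibble::tibble(start = 21, end = 32))
  p <- classify_consequence(mk_pred(edit_at(24, "T")), m2)
  expect_equal(p$consequence, "nonsense")
  expect_equal(p$protein_changes[[1]]$alt_aa, "*")

  # TGT -> TGC is synonymous; touched codon recorded with ref == alt
  p <- classify_consequence(mk_pred(edit_at(29, "C")), m)
  expect_equal(p$consequence, "synonymous")
  expect_equal(p$protein_changes[[1]],
               tibble::tibble(residue = 3L, ref_aa = "C", alt_aa = "C"))
})

test_that("splice disruption outranks coding bystander edits", {
  m <- toy_two_exon()  # intron [27,36]; acceptor AG at 35,36; exon2 at 37..42
  edits <- dplyr::bind_rows(
    edit_at(35, "G"),          # the A of the acceptor AG
    edit_at(39, "C", 9L)       # TGT -> TGC, synonymous bystander
  )
  p <- classify_consequence(mk_pred(edits, editor = "ABE"), m)
  expect_equal(p$consequence, "splice_acceptor")
  expect_equal(nrow(p$protein_changes[[1]]), 0)
  expect_equal(p$splice_residue, 3L)  # first exonic residue right of the intron

  # donor hit
  p <- classify_consequence(mk_pred(edit_at(27, "A")), m)
  expect_equal(p$consequence, "splice_donor")
  expect_equal(p$splice_residue, 2L)  # last exonic residue left of the intron
})

test_that("promoter, intronic and out-of-footprint edits classify as such", {
  m <- toy_two_exon()
  m$promoter <- tibble::tibble(start = 5L, end = 18L)

  p <- classify_consequence(mk_pred(edit_at(10, "T")), m)
  expect_equal(p$consequence, "promoter")
  expect_equal(nrow(p$protein_changes[[1]]), 0)

  p <- classify_consequence(mk_pred(edit_at(31, "T")), m)
  expect_equal(p$consequence, "intronic")

  expect_warning(
    p <- classify_consequence(mk_pred(edit_at(2, "T")), m),
    "outside the gene footprint"
  )
  expect_equal(p$consequence, "no_edit")
})

test_that("non-targeting guides and empty windows yield no_edit", {
  m <- toy_single_exon()
  g <- guide_row("nt", strrep("G", 20), NA, NA_character_,
                 category = "non_targeting")
  p <- annotate_guides(g, m, "CBE")
  expect_equal(p$consequence, "no_edit")
  expect_equal(p$n_edits, 0L)
})

test_that("implementation agrees with the whole-CDS brute-force oracle", {
  set.seed(101)
  agree <- c()
  while (length(agree) < 150) {
    agree <- c(agree, check_random_model_batch(5))
  }
  expect_true(all(agree))
})

test_that("consequences are invariant under reverse-complementing the contig", {
  set.seed(202)
  for (i in 1:8) {
    m <- random_tiny_model(minus = FALSE)
    mf <- revcomp_gene_model(m)
    L <- nchar(m$contig_seq)
    g <- scan_guides(m)
    gf <- scan_guides(mf)
    for (ed in c("ABE", "CBE")) {
      a <- suppressWarnings(annotate_guides(g, m, ed))
      b <- suppressWarnings(annotate_guides(gf, mf, ed))
      # match guides by flipped coordinates
      key_a <- paste(L - g$contig_start - 18L,
                     ifelse(g$strand == "+", "-", "+"), g$protospacer)
      key_b <- paste(gf$contig_start, gf$strand, gf$protospacer)
      idx <- match(key_a, key_b)
      expect_false(anyNA(idx))
      expect_equal(b$consequence[idx], a$consequence)
      expect_equal(b$installs_proline[idx], a$installs_proline)
    }
  }
})

test_that("residue coverage is monotone in the editing window width", {
  set.seed(303)
  cfg <- simulation_config(seed = 303, n_exons = 2, exon_length = 300,
                           intron_length = 80, promoter_length = 60,
                           flank = 40, n_non_targeting = 0, n_intergenic = 0,
                           n_essential_stop = 0, n_nonessential_stop = 0)
  sim <- simulate_gene_and_library(cfg)
  cov_frac <- function(win) {
    p <- suppressWarnings(
      annotate_guides(sim$manifest, sim$model,
                      editor_spec("CBE", window = win))
    )
    res <- unlist(lapply(
      p$protein_changes[p$consequence %in%
                          c("missense", "nonsense", "start_loss", "stop_loss")],
      `[[`, "residue"
    ))
    length(unique(res)) / nchar(sim$model$protein)
  }
  f1 <- cov_frac(c(5, 7)); f2 <- cov_frac(c(4, 8)); f3 <- cov_frac(c(2, 10))
  expect_true(f1 <= f2 && f2 <= f3)
})
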