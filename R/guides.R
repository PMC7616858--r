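# Guide discovery and manifest validation. A guide is one row of a tibble
# with columns guide_id, protospacer (20 nt, protospacer strand 5'->3'),
# pam (3 nt), contig_start (1-based leftmost contig position of the
# protospacer; NA for guides not on this contig), strand, category.

GUIDE_CATEGORIES <- c("targeting", "non_targeting", "intergenic",
                      "essential_stop_control", "nonessential_stop_control")

#' Scan a contig for candidate protospacers
#'
#' Finds every 20-nt protospacer on both strands whose adjacent 3-nt PAM
#' matches `pam` (IUPAC, default NGN). `contig_start` is always the leftmost
#' contig position of the protospacer; for minus-strand guides the
#' protospacer sequence is the reverse complement of the contig slice and
#' the PAM lies immediately left of it on the contig.
#'
#' @param model A [gene_model()] (or a plain contig string).
#' @param region Optional `c(start, end)` or data frame of intervals: keep
#'   only guides whose protospacer overlaps a region interval.
#' @param pam IUPAC PAM pattern (3 nt).
#' @return Tibble of guides ordered by `contig_start`, `+` before `-`,
#'   with `category = "targeting"`.
#' @export
scan_guides <- function(model, region = NULL, pam = "NGN") {
  seq <- if (inherits(model, "gene_model")) model$contig_seq else toupper(model)
  check_dna(seq, "contig")
  L <- nchar(seq)
  out <- list()

  if (L >= 23) {
    s <- seq_len(L - 22L)  # plus strand: protospacer [s, s+19], PAM [s+20, s+22]
    pro <- substring(seq, s, s + 19L)
    pam3 <- substring(seq, s + 20L, s + 22L)
    keep <- !grepl("N", pro, fixed = TRUE) & iupac_match(pam3, pam)
    out$plus <- tibble(protospacer = pro[keep], pam = pam3[keep],
                       contig_start = s[keep], strand = "+")

    s <- 4:(L - 19L)  # minus strand: protospacer [s, s+19], PAM [s-3, s-1]
    pro <- revcomp(substring(seq, s, s + 19L))
    pam3 <- revcomp(substring(seq, s - 3L, s - 1L))
    keep <- !grepl("N", pro, fixed = TRUE) & iupac_match(pam3, pam)
    out$minus <- tibble(protospacer = pro[keep], pam = pam3[keep],
                        contig_start = s[keep], strand = "-")
  }

  guides <- bind_rows(out)
  if (nrow(guides) == 0) {
    return(tibble(guide_id = character(), protospacer = character(),
                  pam = character(), contig_start = integer(),
                  strand = character(), category = character()))
  }
  if (!is.null(region)) {
    if (is.numeric(region) && length(region) == 2) {
      region <- tibble(start = region[1], end = region[2])
    }
    region <- as_tibble(region)
    if (any(region$start < 1 | region$end > L)) {
      abort("region outside contig")
    }
    g_end <- guides$contig_start + 19L
    ov <- rep(FALSE, nrow(guides))
    for (i in seq_len(nrow(region))) {
      ov <- ov | (guides$contig_start <= region$end[i] & g_end >= region$start[i])
    }
    guides <- guides[ov, ]
  }
  guides <- arrange(guides, contig_start, strand)
  gene_tag <- if (inherits(model, "gene_model")) model$gene_id else "contig"
  guides |>
    mutate(
      guide_id = sprintf("%s_%06d_%s", gene_tag, contig_start,
                         ifelse(strand == "+", "fw", "rv")),
      category = "targeting"
    ) |>
    select(guide_id, protospacer, pam, contig_start, strand, category)
}

# contig positions of each protospacer position p (1..20, PAM-distal 5' end)
protospacer_to_contig <- function(contig_start, strand, p) {
  ifelse(strand == "+", contig_start + p - 1L, contig_start + 20L - p)
}

# check targeting guides against the reference; returns tibble of mismatches
reference_mismatches <- function(manifest, model) {
  tg <- manifest[manifest$category == "targeting" & !is.na(manifest$contig_start), ]
  if (nrow(tg) == 0) {
    return(tibble(guide_id = character(), first_mismatch_pos = integer()))
  }
  slice <- substring(model$contig_seq, tg$contig_start, tg$contig_start + 19L)
  expect <- ifelse(tg$strand == "+", slice, revcomp(slice))
  bad <- which(expect != tg$protospacer)
  first_pos <- vapply(bad, function(i) {
    a <- strsplit(tg$protospacer[i], "")[[1]]
    b <- strsplit(expect[i], "")[[1]]
    which(a != b)[1]
  }, integer(1))
  tibble(guide_id = tg$guide_id[bad], first_mismatch_pos = first_pos)
}

#' Validate a guide-library manifest
#'
#' Reports counts per category, invalid PAMs among targeting guides, and
#' (when a gene model is supplied) targeting guides that do not match the
#' reference. Never repairs anything; duplicated guide ids are an error.
#'
#' @param manifest Guide tibble (see [scan_guides()] for columns).
#' @param model Optional [gene_model()] for reference-match checking.
#' @param pam IUPAC PAM pattern targeting guides must satisfy.
#' @return An object of class `manifest_report`: list with
#'   `category_counts`, `invalid_pam`, `reference_mismatch`, `n_guides`.
#' @export
validate_manifest <- function(manifest, model = NULL, pam = "NGN") {
  manifest <- as_tibble(manifest)
  req <- c("guide_id", "protospacer", "pam", "category")
  missing_cols <- setdiff(req, names(manifest))
  if (length(missing_cols)) {
    abort(paste0("manifest lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  dup <- unique(manifest$guide_id[duplicated(manifest$guide_id)])
  if (length(dup)) {
    abort(sprintf("duplicate guide_id(s): %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  unknown <- setdiff(unique(manifest$category), GUIDE_CATEGORIES)
  if (length(unknown)) {
    abort(sprintf("unknown guide category: %s", paste(unknown, collapse = ", ")))
  }

  counts <- manifest |>
    count(category, name = "n") |>
    arrange(match(category, GUIDE_CATEGORIES))

  tg <- manifest[manifest$category == "targeting", ]
  invalid_pam <- tg[!iupac_match(tg$pam, pam), c("guide_id", "pam")]

  mism <- if (!is.null(model)) reference_mismatches(manifest, model) else
    tibble(guide_id = character(), first_mismatch_pos = integer())

  structure(
    list(category_counts = counts, invalid_pam = as_tibble(invalid_pam),
         reference_mismatch = mism, n_guides = nrow(manifest)),
    class = "manifest_report"
  )
}

#' @export
print.manifest_report <- function(x, ...) {
  cat(sprintf("<manifest_report> %d guides\n", x$n_guides))
  print(x$category_counts)
  cat(sprintf("invalid PAM: %d; reference mismatches: %d\n",
              nrow(x$invalid_pam), nrow(x$reference_mismatch)))
  invisible(x)
}

#' Read / write a guide manifest TSV
#'
#' Columns: `guide_id`, `protospacer`, `pam`, `contig_start` (1-based),
#' `strand`, `category`.
#'
#' @param path TSV path.
#' @return `read_guide_manifest()` returns the manifest tibble.
#' @export
read_guide_manifest <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    guide_id = "c", protospacer = "c", pam = "c",
                    contig_start = "i", strand = "c", category = "c"
                  ))
}

#' @rdname read_guide_manifest
#' @param manifest Guide tibble.
#' @export
write_guide_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}
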