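# Synthetic screen generator: a random gene model with canonical introns and
# a promoter, an NGN-tiled guide library with the four control categories,
# ground-truth fitness effects, and overdispersed (negative binomial)
# count tables for a T0 baseline and a day-10-style endpoint.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the analysis is designed for: a
#' semi-saturating NGN guide library of roughly 3000 gene-targeting guides,
#' two editors (ABE/CBE), two cell lines, two independent replicates per
#' screen, ~1000x per-guide T0 coverage, depletion of guides installing
#' deleterious edits at essential residues (l2fc -2, scaled by a
#' Beta-distributed per-guide efficiency), stronger depletion of
#' essential-gene stop controls (l2fc -3), neutrality of synonymous/intronic
#' and control-neutral guides, and negative-binomial count noise with
#' variance `mu + dispersion * mu^2`.
#'
#' @param seed Integer seed; all draws flow from one generator stream.
#' @param n_exons,exon_length,intron_length,promoter_length,flank Gene shape
#'   in nt. `n_exons * exon_length` must be divisible by 3.
#' @param coverage Expected T0 reads per guide (default 1000).
#' @param n_replicates Replicates per timepoint (default 2).
#' @param editors Subset of `c("ABE", "CBE")`.
#' @param cell_lines Names of the simulated lines.
#' @param l2fc_essential True log2 fold-change of guides hitting essential
#'   residues (default -2).
#' @param l2fc_stop_essential True l2fc of essential-gene stop controls
#'   (default -3).
#' @param efficiency_shape Beta(alpha, beta) shape of the per-guide editing
#'   efficiency multiplier (default `c(5, 2)`).
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha mu^2`); 0 gives Poisson counts.
#' @param t0_sdlog Log-sd of the lognormal T0 library representation.
#' @param essential_residues Either a count (>= 1) or a fraction (< 1) of
#'   protein residues that are essential.
#' @param essential_placement `"domain_block"` (contiguous run inside the
#'   helicase-like domain, default) or `"scattered"`.
#' @param n_non_targeting,n_intergenic,n_essential_stop,n_nonessential_stop
#'   Control-category sizes (defaults mirror the study library: 57, 168,
#'   307, 87).
#' @param window,pam Editing window and PAM pattern used for annotation.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_exons = 6L, exon_length = 950L,
                              intron_length = 300L, promoter_length = 300L,
                              flank = 150L,
                              coverage = 1000, n_replicates = 2L,
                              editors = c("ABE", "CBE"),
                              cell_lines = c("lineA", "lineB"),
                              l2fc_essential = -2,
                              l2fc_stop_essential = -3,
                              efficiency_shape = c(5, 2),
                              dispersion = 0.1,
                              t0_sdlog = 0.5,
                              essential_residues = 20,
                              essential_placement = c("domain_block",
                                                      "scattered"),
                              n_non_targeting = 57L, n_intergenic = 168L,
                              n_essential_stop = 307L,
                              n_nonessential_stop = 87L,
                              window = c(4L, 8L), pam = "NGN") {
  essential_placement <- arg_match(essential_placement)
  if (coverage <= 0) abort("coverage must be > 0")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if ((n_exons * exon_length) %% 3 != 0) {
    abort("exon lengths must yield a CDS divisible by 3")
  }
  if (intron_length < 4) abort("introns need >= 4 nt for GT..AG cores")
  structure(
    list(seed = as.integer(seed), n_exons = as.integer(n_exons),
         exon_length = as.integer(exon_length),
         intron_length = as.integer(intron_length),
         promoter_length = as.integer(promoter_length),
         flank = as.integer(flank), coverage = coverage,
         n_replicates = as.integer(n_replicates), editors = editors,
         cell_lines = cell_lines, l2fc_essential = l2fc_essential,
         l2fc_stop_essential = l2fc_stop_essential,
         efficiency_shape = efficiency_shape, dispersion = dispersion,
         t0_sdlog = t0_sdlog, essential_residues = essential_residues,
         essential_placement = essential_placement,
         n_non_targeting = as.integer(n_non_targeting),
         n_intergenic = as.integer(n_intergenic),
         n_essential_stop = as.integer(n_essential_stop),
         n_nonessential_stop = as.integer(n_nonessential_stop),
         window = as.integer(window), pam = pam),
    class = "simulation_config"
  )
}

#' Concordance-study configuration
#'
#' Configuration used to study cross-screen reproducibility of the residue
#' map. Unlike the default configuration (a small block of essential
#' residues, suited to hit-recovery checks), this emulates domain-scale
#' intolerance: one third of protein residues are essential, scattered
#' across the protein, and count dispersion is 0.05, typical of
#' well-powered 1000x-coverage screens. Under these conditions two screens
#' sharing a truth set show high targeting-guide z correlation, while
#' screens with independently drawn truth sets are uncorrelated.
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
concordance_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, essential_residues = 1 / 3,
                    essential_placement = "scattered", dispersion = 0.05, ...)
}

default_domains <- function(protein_length) {
  p <- protein_length
  tibble(
    label = c("exonuclease-like", "helicase-ATP-like", "RQC-like",
              "HRDC-like"),
    start = pmax(1L, as.integer(round(p * c(0.03, 0.30, 0.50, 0.60)))),
    end = as.integer(round(p * c(0.13, 0.46, 0.56, 0.65)))
  )
}

draw_essential_residues <- function(config, protein_length, domains) {
  spec <- config$essential_residues
  n_ess <- if (spec < 1) as.integer(round(spec * protein_length)) else
    as.integer(spec)
  n_ess <- min(n_ess, protein_length)
  if (n_ess == 0) return(integer())
  if (config$essential_placement == "domain_block") {
    dom <- domains[domains$label == "helicase-ATP-like", ]
    lo <- dom$start[1]
    hi <- max(lo, dom$end[1] - n_ess + 1L)
    start <- sample(seq.int(lo, hi), 1)
    seq.int(start, start + n_ess - 1L)
  } else {
    sort(sample.int(protein_length, n_ess))
  }
}

#' Simulate a gene model, guide library and truth set
#'
#' Builds a random contig carrying a promoter and a multi-exon gene with
#' canonical GT/AG introns, scans it for all NGN guides overlapping exons or
#' promoter (the targeting library), appends the four control categories,
#' annotates every guide under each configured editor (combined mode), and
#' assigns ground-truth fitness effects.
#'
#' @param config A [simulation_config()].
#' @return A list of class `screen_simulation`: `model`, `manifest`,
#'   `predictions` (classified, all editors), `truth`, `domains`,
#'   `pathogenicity`, `essential_residues`, `config`.
#' @export
simulate_gene_and_library <- function(config = simulation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)

  cds_seq <- random_orf(config$n_exons * config$exon_length / 3L)
  exon_seqs <- substring(
    cds_seq,
    seq(1L, by = config$exon_length, length.out = config$n_exons),
    seq(config$exon_length, by = config$exon_length,
        length.out = config$n_exons)
  )
  intron_seqs <- replicate(
    max(0L, config$n_exons - 1L),
    paste0("GT", random_dna(config$intron_length - 4L), "AG")
  )

  promoter_seq <- random_dna(config$promoter_length)
  left <- random_dna(config$flank)
  pieces <- character(0)
  starts <- integer(config$n_exons)
  pos <- config$flank + config$promoter_length
  for (i in seq_len(config$n_exons)) {
    starts[i] <- pos + 1L
    pieces <- c(pieces, exon_seqs[i])
    pos <- pos + config$exon_length
    if (i < config$n_exons) {
      pieces <- c(pieces, intron_seqs[i])
      pos <- pos + config$intron_length
    }
  }
  contig <- paste0(left, promoter_seq, paste(pieces, collapse = ""),
                   random_dna(config$flank))
  exons <- tibble(start = starts, end = starts + config$exon_length - 1L)
  promoter <- c(config$flank + 1L, config$flank + config$promoter_length)

  model <- gene_model(
    gene_id = "SYNGENE", contig_id = "synthetic_contig", contig_seq = contig,
    strand = "+", exons = exons, cds = exons, promoter = promoter,
    splice = "error"
  )

  region <- bind_rows(tibble(start = promoter[1], end = promoter[2]), exons)
  targeting <- scan_guides(model, region = region, pam = config$pam)

  mk_controls <- function(n, prefix, category) {
    if (n == 0) return(NULL)
    tibble(
      guide_id = sprintf("%s_%04d", prefix, seq_len(n)),
      protospacer = vapply(seq_len(n), function(i) random_dna(20), character(1)),
      pam = paste0(sample(c("A", "C", "G", "T"), n, TRUE), "G",
                   sample(c("A", "C", "G", "T"), n, TRUE)),
      contig_start = NA_integer_, strand = NA_character_,
      category = category
    )
  }
  manifest <- bind_rows(
    targeting,
    mk_controls(config$n_non_targeting, "NT", "non_targeting"),
    mk_controls(config$n_intergenic, "IG", "intergenic"),
    mk_controls(config$n_essential_stop, "ESC", "essential_stop_control"),
    mk_controls(config$n_nonessential_stop, "NESC", "nonessential_stop_control")
  )

  protein_length <- nchar(model$protein)
  domains <- default_domains(protein_length)
  essential <- draw_essential_residues(config, protein_length, domains)

  # guides at the footprint edge can have all edits in flanking sequence;
  # the classifier's out-of-footprint warning is expected here
  ed <- lapply(config$editors, function(e) {
    suppressWarnings(
      annotate_guides(manifest, model,
                      editor_spec(e, window = config$window, pam = config$pam))
    )
  })
  predictions <- bind_rows(ed)

  # synthetic pathogenicity track loosely tracking the truth: essential
  # residues are usually called pathogenic, the rest mixed
  is_ess <- seq_len(protein_length) %in% essential
  cls <- character(protein_length)
  cls[is_ess] <- sample(c("pathogenic", "ambiguous"), sum(is_ess), TRUE,
                        prob = c(0.9, 0.1))
  cls[!is_ess] <- sample(c("pathogenic", "ambiguous", "benign"), sum(!is_ess),
                         TRUE, prob = c(0.2, 0.25, 0.55))
  score <- numeric(protein_length)
  score[cls == "pathogenic"] <- stats::runif(sum(cls == "pathogenic"), 0.564, 1)
  score[cls == "ambiguous"] <- stats::runif(sum(cls == "ambiguous"), 0.34, 0.564)
  score[cls == "benign"] <- stats::runif(sum(cls == "benign"), 0, 0.34)
  pathogenicity <- tibble(residue = seq_len(protein_length),
                          score = score, class = cls)

  truth <- assign_truth(manifest, predictions, essential, config)

  structure(
    list(model = model, manifest = manifest, predictions = predictions,
         truth = truth, domains = domains, pathogenicity = pathogenicity,
         essential_residues = essential, config = config),
    class = "screen_simulation"
  )
}

#' Assign ground-truth fitness effects
#'
#' Effect model: guides whose combined edit alters at least one essential
#' residue (missense/nonsense/start-loss/stop-loss changes, or a splice
#' disruption whose flanking residue is essential) have true
#' `l2fc = l2fc_essential * efficiency`; essential-gene stop controls have
#' `l2fc_stop_essential * efficiency`; every other guide (synonymous,
#' intronic, promoter, no-edit, non-targeting, intergenic, non-essential
#' stop controls, and protein-altering guides at tolerated residues) is
#' neutral with true l2fc 0. Efficiency is one Beta draw per guide, shared
#' across editors and screens.
#'
#' @param manifest Guide manifest.
#' @param predictions Classified combined-mode predictions for all editors.
#' @param essential_residues Integer vector of essential residues.
#' @param config A [simulation_config()].
#' @return Truth tibble: one row per (guide, editor) with `category`,
#'   `consequence`, `efficiency`, `essential_hit`, `true_l2fc` and a
#'   `class` in essential / tolerated / neutral /
#'   control_essential / control_nonessential.
#' @export
assign_truth <- function(manifest, predictions, essential_residues, config) {
  eff <- tibble(
    guide_id = manifest$guide_id,
    efficiency = rbeta(nrow(manifest), config$efficiency_shape[1],
                       config$efficiency_shape[2])
  )
  preds <- as_tibble(predictions)
  altered <- lapply(seq_len(nrow(preds)), function(i) {
    cq <- preds$consequence[i]
    if (cq %in% c("missense", "nonsense", "start_loss", "stop_loss")) {
      pc <- preds$protein_changes[[i]]
      pc$residue[pc$ref_aa != pc$alt_aa]
    } else if (cq %in% c("splice_donor", "splice_acceptor")) {
      r <- preds$splice_residue[i]
      r[!is.na(r)]
    } else {
      integer()
    }
  })
  ess_hit <- vapply(altered, function(r) any(r %in% essential_residues),
                    logical(1))

  truth <- preds[, c("guide_id", "category", "editor", "consequence")] |>
    mutate(essential_hit = ess_hit) |>
    inner_join(eff, by = "guide_id") |>
    mutate(
      true_l2fc = dplyr::case_when(
        category == "essential_stop_control" ~
          config$l2fc_stop_essential * efficiency,
        category == "targeting" & essential_hit ~
          config$l2fc_essential * efficiency,
        .default = 0
      ),
      class = dplyr::case_when(
        category == "essential_stop_control" ~ "control_essential",
        category == "nonessential_stop_control" ~ "control_nonessential",
        category %in% c("non_targeting", "intergenic") ~ "neutral",
        essential_hit ~ "essential",
        consequence %in% c("synonymous", "intronic", "promoter", "no_edit") ~
          "neutral",
        .default = "tolerated"
      )
    )
  truth
}

#' Simulate screen count tables
#'
#' For every configured (cell line, editor) screen: a per-guide T0 abundance
#' is drawn lognormal around `coverage` (mean exactly `coverage`); the
#' endpoint expectation is the T0 share times `2^true_l2fc`, renormalized to
#' the sequencing depth (`n_guides * coverage`); counts are drawn
#' negative-binomially (variance `mu + dispersion mu^2`) independently per
#' replicate and timepoint.
#'
#' @param manifest Guide manifest.
#' @param truth [assign_truth()] output covering every guide and editor.
#' @param config A [simulation_config()].
#' @param seed Optional seed for the count noise (defaults to the current
#'   RNG stream).
#' @return List of class `screen_counts`: `counts` (tibble `guide_id` +
#'   one column per sample) and `samples` (sample sheet).
#' @export
simulate_screen_counts <- function(manifest, truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$dispersion < 0) abort("dispersion must be >= 0")
  n <- nrow(manifest)
  depth <- n * config$coverage
  draw <- function(mu) {
    if (config$dispersion == 0) rpois(n, mu) else
      rnbinom(n, mu = mu, size = 1 / config$dispersion)
  }

  counts <- tibble(guide_id = manifest$guide_id)
  samples <- list()
  for (cl in config$cell_lines) {
    for (ed in config$editors) {
      tr <- truth[truth$editor == ed, ]
      tr <- tr[match(manifest$guide_id, tr$guide_id), ]
      stopifnot(!anyNA(tr$true_l2fc))
      a <- rlnorm(n, meanlog = log(config$coverage) - config$t0_sdlog^2 / 2,
                  sdlog = config$t0_sdlog)
      mu0 <- a / sum(a) * depth
      w <- a * 2^tr$true_l2fc
      mu1 <- w / sum(w) * depth
      for (tp in c("T0", "Tend")) {
        mu <- if (tp == "T0") mu0 else mu1
        for (r in seq_len(config$n_replicates)) {
          sid <- paste(cl, ed, tp, paste0("R", r), sep = "_")
          counts[[sid]] <- draw(mu)
          samples[[sid]] <- tibble(sample_id = sid, cell_line = cl,
                                   editor = ed, timepoint = tp, replicate = r)
        }
      }
    }
  }
  structure(list(counts = counts, samples = bind_rows(samples)),
            class = "screen_counts")
}

#' @export
print.screen_simulation <- function(x, ...) {
  cat(sprintf(
    "<screen_simulation> %d guides (%d targeting), %d essential residues, editors: %s\n",
    nrow(x$manifest), sum(x$manifest$category == "targeting"),
    length(x$essential_residues), paste(x$config$editors, collapse = ", ")
  ))
  invisible(x)
}
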