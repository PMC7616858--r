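---
title: "Methods: base-editing saturation-mutagenesis screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-editing saturation-mutagenesis screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experiment being modelled

A base-editing saturation-mutagenesis screen tiles a gene of interest with
every usable sgRNA, expresses an adenine base editor (ABE, A→G) or cytosine
base editor (CBE, C→T) in cells that depend on the gene for growth, and
sequences the guide cassette at a baseline timepoint (T0, collected a few
days after infection) and after a selection window (here, a day-10-style
endpoint). A guide whose predicted edit damages a residue the cell needs
drops out of the library; a guide whose edits are synonymous or intronic
does not. Because single-nucleotide edits — unlike nuclease knockouts — can
produce specific missense variants, the depletion pattern resolves *which
residues* are required, not merely whether the gene is essential.

`bescan` implements the analysis side of this design: predicting the edits a
guide installs, classifying their protein consequence, scoring depletion,
projecting scores onto the protein, and testing where intolerant residues
concentrate. A generative simulator with known ground truth stands in for
the controlled-access sequencing data of a real screen, so every claim the
package makes about itself is testable in code.

## Edit prediction and consequence classification

**Editing window.** Editable bases are the editor's substrate base on the
protospacer strand within an inclusive window of protospacer positions,
counted 1–20 from the PAM-distal 5′ end. The default window is 4–8, the
conventional high-activity window for the NGN-PAM editor generation modelled
here; because the annotation (and therefore every downstream residue
assignment) depends on it, the window is an explicit parameter of
`editor_spec()` and is recorded in every pipeline manifest rather than
hard-coded.

**Combined versus individual predictions.** Real editors frequently convert
several window bases at once ("bystander" edits). The *combined* prediction
— every editable window base converted simultaneously — is the primary
annotation used for scoring; *individual* per-base predictions are retained
for reporting. This mirrors how saturation screens display "individual and
combined putative edits" side by side.

**Consequence priority.** A combined edit can straddle classes (e.g. a
splice-core hit plus a synonymous bystander). One consequence is assigned
per prediction using the priority

`splice_donor = splice_acceptor` &gt; `nonsense` &gt; `start_loss` &gt;
`stop_loss` &gt; `missense` &gt; `synonymous` &gt; `promoter` &gt;
`intronic` &gt; `no_edit`,

i.e. more disruptive outcomes mask less disruptive ones. Splice annotation
is deliberately limited to the canonical 2-nt GT/AG intron cores; extended
splice-region effects are out of scope. Promoter-targeting guides receive a
`promoter` consequence with no protein change. Edits falling entirely
outside the gene footprint give `no_edit` with a warning, never an error,
because tiled libraries legitimately contain edge guides. `installs_proline`
is flagged separately because proline-introducing missense edits are a
recognised source of misfolding-driven loss of function that sits outside
any per-residue effect logic.

**Verification strategy.** The classifier works incrementally (only the
affected codons are re-translated). The test-suite checks it against a
deliberately different brute-force oracle that mutates the entire contig
string, re-extracts and re-translates the whole CDS, and diffs the proteins;
agreement is required to be exact over ≥1000 random (gene, guide, editor)
triples, including minus-strand genes. A strand-symmetry property
(reverse-complementing the contig and flipping all annotations leaves every
consequence unchanged) guards the coordinate arithmetic.

**Coordinates.** All coordinates, internal and external, are 1-based
inclusive. This is a deliberate design choice for an R package: GFF3,
IRanges and GenomicRanges are all 1-based inclusive, and keeping a single
convention end-to-end removes an entire class of off-by-one conversions.

## Scoring model

For each sample, `RPM_g = (count_g + c) / Σ(count + c) × 10⁶` with
pseudo-count `c = 1` added to raw counts; RPM is averaged arithmetically
across replicates within a timepoint; guides with mean raw T0 reads
strictly below 100 are discarded ("fewer than 100" is strict: 100 passes,
99 fails, and the suite pins this boundary exactly); passing guides get
`l2fc = log2(RPM_end / RPM_T0)` and a z-score standardised per screen (one
screen = one cell line × one editor) using the sample standard deviation
over that screen's passing guides.

Choices worth stating explicitly:

- **Pseudo-count placement and size.** Added to raw counts before RPM,
  value 1. Any positive value regularises zero counts; 1 is the smallest
  integer choice and its effect vanishes at screen-scale depths.
- **Mean-centring.** `z = (l2fc − mean)/sd` by default. The literal reading
  "l2fc divided by its standard deviation" (no centring) is available as
  `center_z = FALSE`; both are recorded in the run manifest. With centring,
  z of passing guides has mean 0 and sd 1 per screen, which the tests
  assert.
- **Filter on the mean of T0 replicates**, not on any single replicate:
  the replicate average is what enters the fold-change, so it is the
  quantity whose reliability the filter protects.
- **T0 as denominator.** Depletion is endpoint versus the day-5 baseline
  pellet, not versus the plasmid pool.
- **Compositional shift.** RPM renormalisation means that when part of the
  library truly depletes, every l2fc shifts by a small positive constant.
  z-scores are invariant to this; raw l2fc comparisons to truth in the
  tests are made up to that constant.

Control QC reports, per screen, the median z of each control category and
the rank-based AUROC separating essential-gene stop controls from
non-essential-gene stop controls — the probability that a random essential
control scores lower. The AUROC implementation (Mann–Whitney rank form,
ties counted half) is tested against a naive pairwise computation.

## Residue mapping, hits and enrichment

Guides with protein-altering consequences contribute their z to every
residue in their predicted protein changes; splice-disrupting guides
contribute to the nearest exonic residue flanking the affected intron
boundary (a display convention — splice hits remain identifiable by their
consequence). Synonymous, intronic, promoter and no-edit guides contribute
nowhere.

- **Aggregation is min-z by default**: one strongly depleted guide is
  enough to mark a residue intolerant, matching the per-sgRNA displays used
  in this field; mean aggregation is available.
- **The hit threshold is z ≤ −2** by default, configurable and always
  reported alongside raw aggregate z so that no information is destroyed by
  the binarisation.
- **Residues with no contributing guide carry `NA`**, not `FALSE`: given
  variable guide efficiency, absence of evidence is not evidence of
  tolerance.
- **Enrichment** is a one-sided hypergeometric over-representation test of
  hit residues within a domain (or pathogenicity class), with the universe
  restricted to guide-covered residues for the same reason. The
  `stats::phyper` tail is verified against exhaustive enumeration of all
  hit placements for every universe of up to 12 residues, and a worked
  4-residue example (2 hits, both inside a 2-residue domain, p = 1/6) is
  pinned in the tests.
- **Concordance** between screens is the Pearson r (and r²) of z over the
  intersection of guides passing filters in both.

The stop codon is addressed as residue `protein_length + 1`; a stop-loss
contribution folds onto the last real residue for display. Contributions
beyond that are an error, catching residue/protein mismatches early.

## The simulator: what it emulates and what it does not

`simulate_gene_and_library()` builds a random contig containing a promoter
and a multi-exon gene with canonical GT/AG introns and a clean ORF, scans
it for all NGN guides overlapping exons or promoter, appends the four
control categories, annotates every guide under each editor with the same
classifier used in analysis (the classifier itself is validated against an
independent oracle, so this self-consistency is safe), and assigns truth:

- guides whose combined edit alters ≥1 *essential residue* deplete with
  `l2fc = −2 × efficiency`;
- essential-gene stop controls deplete with `l2fc = −3 × efficiency`;
- everything else — synonymous, intronic, promoter, no-edit, non-targeting,
  intergenic, non-essential stop controls, and protein-altering guides at
  tolerated residues — is neutral (true l2fc 0).

Efficiency is one Beta(5, 2) draw per guide (mean ≈ 0.71), shared across
editors and screens: guide-intrinsic editing activity is the dominant,
reproducible source of effect-size variation acknowledged in these screens.
Counts are negative binomial with variance μ + αμ² (the standard
overdispersion model for sequencing counts), T0 abundance is lognormal
around the configured coverage with the endpoint renormalised to constant
sequencing depth, and all draws flow from a single seeded generator stream
so that any run replays exactly.

**Default configuration = study conditions.** ~3000 targeting guides over a
1899-residue protein (a six-exon, 5.7-kb CDS), control categories of 57
non-targeting / 168 intergenic / 307 essential-stop / 87 non-essential-stop
guides, two editors, two cell lines, two replicates, 1000× coverage, 20
essential residues placed as a contiguous block inside the helicase-like
domain of the synthetic domain track, dispersion α = 0.1. Under this
configuration the suite requires essential-vs-neutral guide AUROC ≥ 0.9, a
neutral hit rate ≤ 5% at z ≤ −2, control AUROC ≥ 0.95, and significant hit
enrichment in the seeded domain.

**Concordance study configuration.** Cross-screen reproducibility is a
property of the *fraction of guides carrying real signal*: with only 20
essential residues, almost every targeting guide is pure noise and
cross-line r² is necessarily tiny regardless of data quality. To study
concordance under domain-scale intolerance — the regime real essential-gene
screens operate in — `concordance_config()` makes one third of residues
essential (scattered) and uses dispersion α = 0.05, typical of well-powered
high-coverage screens. These two values were fixed at design time from the
variance arithmetic (signal share vs log-count noise), not fitted to any
observed run. Under this configuration, screens sharing a truth set give a
targeting-guide z r² around 0.6, while screens with independently drawn
truth sets give r² near 0 — by construction, because independent truths
have zero effect covariance. Controls are excluded from this comparison:
their depletion is deterministic given the manifest and would manufacture
concordance even between unrelated truths.

**What the simulator does not model:** read-level sequencing and alignment,
editor-specific efficiency learned from sequence context, infection and
selection dynamics (absorbed into the T0 abundance distribution), dose
gradation of effects by residue, off-target editing, and pre-existing
variants (the wild-type-genome assumption). Passing tests therefore
demonstrate the correctness and statistical behaviour of the *analysis*,
not the biological fidelity of any particular screen.

## Numerical and degenerate-input behaviour

- Ties in control-guide ranking break lexicographically by guide id; ties
  in AUROC count one half.
- Fewer than three passing guides in a screen is an error (the standard
  deviation would be meaningless), as is a missing control category, an
  empty enrichment universe, or fewer than three shared guides in a
  concordance computation.
- A sample of all-zero counts is handled by the pseudo-count (uniform RPM);
  it is only an error if the pseudo-count is set to 0.
- Dispersion 0 switches the count model to Poisson; as dispersion shrinks,
  observed l2fc converges to truth up to the compositional constant (a
  tested property).
- Pipeline outputs are plain TSVs with a commented header carrying the
  package version and a canonical-JSON config hash; `rerun_from_manifest()`
  reproduces a run byte-for-byte, and the hash is type-stable across the
  JSON round-trip (integer/double storage of the same value cannot change
  it).

## Problem sizes used by the checks

The oracle-equivalence sweep uses ≥1000 random triples on tiny genes
(8–14 codons); scoring exactness uses 100 random 50-guide × 4-sample
matrices at 10⁻⁹ relative tolerance; parameter recovery runs one default
simulation (~3700 guides × 8 samples); the concordance contrast uses one
library with ten independent truth/noise replicates; enrichment exactness
enumerates every universe up to 12 residues. These sizes keep the full
suite under two minutes on a single CPU while leaving each property
sharply testable.

## Known limitations

- Single-transcript gene models only; isoform-aware annotation is out of
  scope.
- Splice consequences cover the canonical 2-nt cores only.
- UTR-exon edits are classified with the coarse `intronic` label; the
  synthetic fixtures contain no UTRs.
- The per-residue map treats multi-residue guides by assigning their z to
  every altered residue, which smears signal across neighbours at the
  resolution of one editing window.
- SpliceR-style control-guide design scores (cDNA disruption, editor
  activity) are inputs; only their combination metric
  `d × (ABEscore + CBEscore)` and the top-k selection are implemented.
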