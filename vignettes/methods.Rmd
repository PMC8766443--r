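---
title: "Split-pool antibody-tag quantification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-pool antibody-tag quantification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement

splitADT models sequencing-based single-cell protein quantification with
DNA-barcoded antibodies and split-pool combinatorial indexing. Cells are
stained with a panel of antibodies, each conjugated to an oligo carrying an
antibody-identifying barcode and a unique molecular identifier (UMI). The
stained cells are then distributed at random across a plate of wells, where
a well-specific barcode is ligated onto every antibody tag in the well; the
cells are pooled, redistributed, and ligated again; a final well barcode is
appended by PCR. Every amplicon therefore carries an antibody barcode plus
three well barcodes, and all molecules bound to the same cell share the
same barcode triple. Grouping reads by triple reconstructs single cells
without microfluidics; counting distinct UMIs per (cell, antibody)
quantifies antigen abundance.

Two spike-in control populations audit the chemistry:

* **hashtag-only controls (HT2)** — cells stained only with one hashtag
  antibody, mixed in before the first split (5% of the initial pool by
  default). Any marker-antibody signal appearing on these cells measures
  antibody dissociation/re-binding and barcode hopping.
* **late-spike controls (HT3)** — cells stained only with a second
  hashtag, added *after* the first ligation round (5% of the pool). They
  can never legitimately carry a round-1 barcode, so any called cell
  traceable to them measures failure of the splint-blocking step.

Multiple samples are pooled by staining each with a distinct *combination*
of hashtag antibodies before mixing; with four hashtags, up to 15 samples
can be coded by non-empty subsets. The package assigns subsets
deterministically — singletons in hashtag order, then pairs, then triples,
lexicographically — so ten samples use the four singletons and six pairs.

# Collision mathematics and the loading rule

With `n` cells deposited uniformly among `m = w1 * w2 * w3` barcode
triples, the probability that a given cell shares its triple is

    p_coll = 1 - (1 - 1/m)^(n-1)  ~=  1 - exp(-(n-1)/m),

the Poisson-process view of doublet formation. `max_loading(m, f)` applies
the dilution rule `n = floor(f * m)`: at the default 2% occupancy of a
96^3 = 884,736-triple layout, up to 17,694 cells may be loaded and the
collision fraction stays just under 2%. `expected_collision_fraction()`
exposes both the exact and Poisson forms;
`simulate_collision_fraction()` cross-checks them by Monte-Carlo.

# The forward simulator

The simulator is the package's source of ground truth and is itself tested
code. Its generative model, stage by stage:

* **Abundance.** The number of bound antibodies of each species on a cell
  is Poisson with a log-normal rate: `x ~ Pois(exp(N(log mu, sigma)))`,
  where `mu` is the cell type's mean copy number and `sigma`
  (`dispersion`, default 0.35) captures biological plus staining
  variability. Every antibody also receives a low non-specific background
  (`background_mean`, default 1 copy), so isotype controls and stray
  hashtags have realistic nonzero counts. No particular distribution is
  canonical for antibody capture; the log-normal/Poisson mixture is the
  standard overdispersed choice and leaves CLR-space geometry realistic.
* **Hashtags.** Regular cells carry their sample's hashtag subset at
  `hashtag_mean` (60) copies; spike-in controls carry only their control
  hashtag at `control_hashtag_mean` (150) copies, enough to pass the
  cell-calling UMI floor on hashtag signal alone.
* **Split-pool.** Each cell draws uniform wells for rounds 1, 2 and the
  PCR round; late-spike cells have no round-1 well. Each molecule
  inherits its cell's path, then per-molecule noise applies: ligation of
  rounds 1 and 2 succeeds with `ligation_success_prob` (default 1 — the
  chemistry is efficient, and the parameter is free because no efficiency
  is quantified); with `swap_rate` a molecule adopts the *complete* well
  path of a random other cell. Swapping is modelled as dissociation
  before the first split because that is the variant observable in the
  hashtag-only control readout (a swapped molecule lands inside another
  cell's called profile); a partial-path swap would only scatter
  molecules into orphan triples that the UMI floor discards. With
  `blocking_failure_prob` a late-spike molecule picks up a random
  round-1 barcode from the pooled mix.
* **Sequencing.** PCR is modelled as per-molecule read multiplicity
  (geometric with mean `mean_reads_per_molecule`, default 1.5) rather
  than cycle-by-cycle amplification; the 14-cycle protocol figure is kept
  as metadata only, since after bead cleanup and loading normalisation
  the observable is duplication, not yield. Reads are fixed-length
  (100 nt / 50 nt); substitution errors are i.i.d. per base
  (`seq_error_rate`, default 0.002, a typical short-read scale); no
  indels, because ligation products are fixed-length and the dominant
  error mode of the platform is substitution. Qualities are constant and
  ignored downstream.

What the generator does **not** emulate: ambient free antibody, cell
doublets from aggregation, well-to-well volume or efficiency gradients,
ligation chimeras, index hopping between libraries, and read-depth
variation across lanes. Passing tests therefore demonstrate correctness of
the *computational* pipeline under a faithful error model, not robustness
to every artifact of real libraries.

# Demultiplexing

* **Whitelists and correction.** Well-barcode whitelists are generated by
  rejection sampling at minimum pairwise Hamming distance 3 (8-nt
  barcodes), so radius-1 correction is unambiguous: any single
  substitution maps back to exactly one entry. Observed segments are
  corrected within radius `correction_radius` (default 1); ties at the
  minimum distance are rejected, never broken arbitrarily —
  reproducibility is preferred over a fraction of a percent of yield.
  `N` bases count as mismatches. The barcode-segment lengths (8-nt well
  barcodes, 15-nt antibody barcode, 10-nt UMI, 6-nt linkers) are
  configurable defaults chosen at the scale commercial reagents use.
* **Cell calling.** One candidate cell per distinct corrected triple;
  triples with fewer than `min_umi` total UMIs (default 10) are dropped.
  An explicit floor was chosen over knee-point detection because the
  design's collision math already fixes expected cells, and a fixed,
  config-visible threshold is reproducible; cells are identifiable from
  roughly a hundred UMIs, so 10 is permissive.
* **UMI collapse.** Default `directional` with 1 mismatch: merge UMI B
  into A when `Hamming(A,B) <= 1` and `count(A) >= 2*count(B) - 1`, then
  count connected components. This is the established network-based rule
  for separating sequencing-error satellites from genuine molecules.
  `exact` counting is available; on error-free data it is the exact
  inverse of the simulator (directional can merge the rare pair of true
  molecules whose random UMIs differ by one base, which is why the
  round-trip tests use it).
* **Accounting.** Every read is either assigned or tallied in a discard
  ledger by first failing stage (truncated, round-1/2/3 or antibody
  uncorrectable); ledger totals always equal the input read count.

# Quantification and QC

Counts are transformed per cell by the centered log-ratio,
`clr_i = log((x_i + c) / g(x + c))` with `g` the geometric mean across the
cell's antibodies and pseudocount `c = 1` (zeros are ubiquitous in
antibody counts). Rows of the log form sum to zero; the transform is
invariant to per-cell depth. The no-log variant (plain ratio to the
geometric mean) is available behind `log = FALSE` for strict fidelity to
the ratio form of the transform; the log form is the default because it
is what "centered log-ratio" means and what downstream linear methods
(PCA, k-means) assume. Natural log is the default base.

Hashtag positivity is called per hashtag by a two-class 1-D k-means split
with deterministic extreme-value initialisation — threshold-free and
reproducible — with a fixed-threshold mode as override. A cell's positive
set is matched against the sample code exactly; supersets containing two
or more full codes are `multi_sample`, anything else unmatched is
`undetermined`.

`control_qc()` reports the three control readouts: late-spike cells
called (must be 0 when blocking holds), marker CLR on hashtag-only cells
versus ordinary cells (swap leakage), and the isotype score distribution.
In simulation the control attribution comes from ground truth via the
barcode triple; late-spike fragments (which have no legitimate full key)
are recognised by their round-2/round-3 well pair.

# Downstream analysis

* **PCA** is centered, unscaled, with a deterministic sign convention
  (largest-magnitude loading positive).
* **k-means** uses best-of-10 restarts under a fixed seed; the
  benchmarking design clusters k = 4 groups (two cell lines, hashtag-only
  controls, non-specific cells) on the top-3 PCs.
* **t-SNE** runs on the CLR matrix with PCA initialisation (top-2 scores
  rescaled to the conventional 1e-4 spread), perplexity 30 by default —
  a standard value; none is prescribed by the underlying procedure.
* **Gating** is hierarchical: each gate intersects its parent's mask with
  a marker threshold, derived by the same two-class split *within the
  parent population* when not given explicitly. Gates therefore always
  nest. The threshold for a marker with no negative class in the parent
  (e.g. CD3 inside an already CD19-gated population) should be estimated
  on a broader ancestor and passed explicitly, as the gating vignette
  tests do.
* **Kappa-lambda**: the ratio of kappa- to lambda-positive cells inside a
  B-cell gate; 1-2 is reported as normal, above 2 kappa-expanded, below 1
  lambda-expanded, the usual clonality screen.
* **Non-specific flagging** selects the principal component on which the
  control markers load most strongly in a *common* direction (squared
  signed loading sum — a contrast between two controls is not a
  non-specific signature), orients it positive, and flags cells beyond
  2.5 MADs. The cutoff is a conventional robust-outlier choice; such
  cells are identified qualitatively in practice.

# Built-in study designs

`fixture_config()` ships three scenarios whose defaults *are* the study
conditions:

* `two_lines`: 1,900 regular cells (a 2,000-cell initial pool with the 5%
  hashtag-only spike; 5% late spike on top), 49/49% two cell lines with
  distinguishing markers (CD4/CD45/CD28 vs CD56/CD155/CD29), 2%
  non-specifically stained cells carrying isotype and residual
  late-hashtag signal, 7-antibody marker/isotype panel plus hashtags,
  96-well rounds.
* `ten_patients`: ten samples coded by combinations of four hashtags over
  a 29-antibody hematology panel (28 markers + isotype), with a
  kappa-restricted B-lymphoproliferative sample and a CD4+CD25+PD1+
  T-lymphoma-like sample among normal mixtures; 150 cells per sample at
  test scale.
* `controls_only`: 300 hashtag-only plus 300 late-spike cells and no
  regular samples.

Test-scale sizes (a few hundred to two thousand cells, roughly half a
million reads for the full benchmarking design) were chosen so the whole
suite runs comfortably on a laptop while keeping binomial sampling errors
small relative to the effects tested.

# Known limitations

* Barcode collisions are resolved statistically (loading rule), not
  deconvolved; colliding cells appear as mixed profiles.
* The swap model collapses several physical mechanisms (dissociation,
  PCR chimera, index hop) into one between-cell reassignment rate.
* Blocking failure scatters a late cell's molecules across round-1
  barcodes, so detecting it requires permissive cell calling
  (`min_umi = 1`); with the default floor such fragments are silently
  discarded — which is also why the control works as a purity check.
* Positivity by two-class splitting assumes each gated marker is bimodal
  in the population it is estimated on; unimodal populations must be
  gated with explicit thresholds.
* The t-SNE map is for visualisation; no quantitative claim is derived
  from its geometry.

```{r, eval = FALSE}
library(splitADT)
fx <- fixture_config("two_lines", seed = 1)
res <- run_pipeline(fx$config, fx$schema, "run_two_lines", seed = 1)
res$qc
```
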