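---
title: "Methods: conservation of PTM-site residues across nested clades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation of PTM-site residues across nested clades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmevoscan)
```

# The model and its assumptions

`ptmevoscan` asks whether post-translational modification (PTM) status —
specifically methylation, acetylation and ubiquitination ("MAU") of
lysines and arginines — drives the evolutionary conservation of those
residues, separately in ordered and intrinsically disordered regions,
and separately at each level of a strictly nested series of taxonomic
clades centred on a reference species.

The statistical model is deliberately simple and exact. At a clade
level, consider all residues of the relevant letter(s) in one region
class among proteins included at that level (a protein is included iff
it has an ortholog in at least one of the level's species). Of these
`N` residues, `K` are human PTM sites of the type under test. The
"conserved" subset of size `n` contains `k` sites. Under the null that
conservation is blind to PTM status, `k` follows a hypergeometric
distribution; the reported enrichment P-value is the exact upper tail
`P(X >= k)`, computed by log-space summation of `lchoose` terms so that
values like 1e-82 are represented exactly on the log10 scale rather
than underflowing. Bonferroni correction is `alpha / m` per declared
test family.

Assumptions worth stating:

* **Conservation is read literally.** "Completely conserved" means
  every counted ortholog row carries the human residue (strict mode)
  with no gap in any counted row. A clade species without an ortholog
  row is *ignored*, not treated as non-conserving: gene absence is not
  sequence divergence at a site — but a level with zero ortholog rows
  yields `FALSE`, since nothing attests conservation.
* **Human-anchored identity.** Strict mode requires identity to the
  *human* residue, not mere column unanimity; the analysis tracks the
  fate of human site residues.
* **"Newly emerged" uses the immediately wider level.** A residue is
  newly emerged at level *i* iff conserved at *i* and not at *i + 1*
  (always `FALSE` at the outermost level). "Not conserved across a more
  ancient, wider clade" could also be read as "not at *any* wider
  level"; under nested conservation the two readings coincide, and the
  adjacent-level definition is unique and testable, so it was adopted.
* **Nesting caveat.** Conservation at a wider level implies it at a
  narrower one only when the narrower level has at least one ortholog
  row; the property tests construct alignments where every species has
  a row, which is the regime in which the invariant is meaningful.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `disorder_threshold` | 0.5 | per-residue disorder score (in [0,1]) at or above which an unstructured residue is `disordered`; the conventional predictor cut-off |
| `evalue_max` | 1e-4 | strict upper bound for reciprocal-best-hit e-values |
| `bias_threshold` | 1e-10 | binomial tail for the prion-like compositional-bias call |
| `mask_range` | [5, 10] | retained range for per-column alignment-quality scores in [0, 10] |
| `homopeptide_min` | 3 | minimum identical-residue run length |
| `alpha` | 0.05 | family-wise error rate before Bonferroni division |
| `family_size` | 11 | Bonferroni family for the per-level series (one test per level) |

Every one of these lives in `run_config()` and nowhere else in the
pipeline. The corrected thresholds printed in the source analyses imply
family sizes (7, 36, 12, 20) that are recorded as `bonferroni_presets`
— presets, not hard-coded truths, because the defining supplement is
not machine-readable here.

Residue substitution classes for class-mode conservation are
`METHYL = {K, R}` (arginine is also methylatable) and
`ACETYL = {K, A, G, M, S, T}` (residues that can also be acetylated).
Class mode requires the human residue and every ortholog character to
be class members, gaps still forbidden; strict conservation therefore
implies class conservation whenever the human residue is in the class,
which is verified as a property test.

# The compositional-bias scorer

The prion-like call is a simplified re-implementation of a
low-probability subsequence scan: over all windows of length 15–500
(clipped at the sequence length), find the window minimising the
binomial upper tail of observing at least the window's count of target
residues given the background frequency of the target set; a protein is
prion-like when the minimum over the residue sets {N}, {Q}, {N, Q} is
at or below 1e-10. Background frequencies default to the composition of
the input protein set. This scorer is *not* expected to agree
numerically with any external binary (window bounds and background
model of the original tool are unstated); it is monotone in the target
count at fixed window length, which is what the tests pin down, and the
call is protein-level because downstream analyses treat prion-like
status as a protein flag. The scan runs over the whole sequence rather
than only annotated disordered sub-sequences; with planted Q-runs
inside disordered spans (the generator's behaviour) the two choices
agree, and the whole-sequence scan keeps the call independent of the
annotation stage.

# What the synthetic generator emulates — and what it does not

`generator_params()` describes the stated world:

* an 11-level nested hierarchy with 40 species standing in for the
  study's 380 (desk-scale: the full pipeline plus 20 seeded recovery
  replicates and 2000 null tests must fit a small CPU budget);
* 50 proteins of 150–300 residues, ~40% of each protein in one
  contiguous disordered span with K/R frequencies boosted threefold;
* MAU site densities of 0.4 / 0.7 / 1.0 sites per 100 residues
  (methylation / acetylation / ubiquitination), matching the source
  data's ordering (ubiquitination most numerous) and giving > 200
  sites per default bundle; sites of different types can coincide,
  which is how multiple-MAU residues arise;
* per-level conservation survival probabilities of 0.9 for site
  columns versus 0.5 for background columns, applied innermost-out
  with "once broken, stays broken", so generated conservation is
  nested by construction and the pipeline's nesting invariant is
  falsifiable only by pipeline bugs;
* ortholog presence probability 0.9 per species, gap rate 0.02 per
  cell with gaps avoiding site columns by default (so truth labels and
  pipeline calls can be compared exactly).

These values were fixed before the acceptance runs and not revisited.
What the generator does **not** emulate: realistic indel evolution or
substitution matrices, phylogenetic branch lengths, isoform numbering
conflicts between PTM databases, or human-row gaps (ortholog rows are
deletions relative to the human sequence). A green recovery test
therefore establishes that the pipeline detects a planted
conservation-enrichment signal of the stated size — it does not
establish anything about the biological effect sizes in real
proteomes, which are unreachable without the full multi-proteome
inputs.

# Numerical choices and degenerate inputs

* Hypergeometric tails: exact log-space summation; the independent
  test oracle is direct enumeration with `choose()` ratios (and
  `phyper` as a second cross-check). Tails share the observed term:
  `P(enrich) + P(deplete) - P(X = k) = 1`.
* Best-hit ties after (e-value, bit score) yield *no* ortholog call
  rather than an arbitrary pick, for reproducibility; self-hits are
  discarded before selection. The e-value threshold is strict (`<`),
  so a hit at exactly 1e-4 fails.
* Empty sample in an enrichment test: `n = 0` returns a
  `not_significant` result with a warning, never an error; an empty
  *population* is an error naming the selector.
* Zero denominators in percentage summaries render `"NA"`.
* Window bounds beyond the sequence length in the bias scorer are
  clipped, not errors.
* Masked columns force `conserved = FALSE` and are flagged, so masking
  can only shrink the conserved set (a tested property) and masked and
  unmasked analyses are both reproducible from one run.
* All intervals are 1-based inclusive in memory; BED files are 0-based
  half-open on disk and converted at the boundary.
* Pipeline outputs serialise P-values at fixed precision
  (`%.6f` on the log10 scale) so identical configurations give
  byte-identical runs.

# Design choices where the design was genuinely open

* **Sample/population definitions of the clade-level test.** The
  defining supplementary text is not available here; the implemented
  default follows the one-sentence definition — conserved residues of
  the same letter(s) as the modification, in the same region, among
  included proteins, with sites as the marked subset — and
  `run_test()` accepts arbitrary declarative selectors so alternative
  definitions are configuration, not code.
* **A third selector.** The declarative test spec carries an explicit
  `success` selector besides population and sample: the region
  preference test (sample = ordered residues, marked = modified
  residues) cannot be expressed with two selectors alone.
* **Age classification universe.** "Outside the clade" means the
  outermost level's species minus the level's species: nothing beyond
  the analysed species panel is observable, so at the outermost level
  every included protein is vacuously "new" and is flagged as such.
* **Unknown modification types** are preserved as `other:<name>`
  rather than rejected, so rare PTMs flow through the same machinery.
* **Methylation is split by residue letter** (`methylation_K`,
  `methylation_R`) because the two letters have distinct conservation
  behaviour; acetylation and ubiquitination are lysine-only in
  practice and keep their names.

# Known limitations

* Clade-level P-values of the source study are not reproducible at
  desk scale (380 proteomes, three PTM databases); the package's
  quantitative claims are confined to what its tests compute.
* The bias scorer is a stand-in, not a reimplementation, of the
  original compositional-bias tool.
* The RBH stage consumes similarity hit tables; it does not run the
  similarity search itself, and orthology is pairwise (no tree
  reconciliation).
* Alignments are consumed, not constructed; the human row of a family
  alignment must de-gap to the reference sequence.
* PTM positions must arrive reconciled to the reference isoform
  numbering; the readers validate residue-at-position identity and
  reject mismatches rather than attempting reconciliation.
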