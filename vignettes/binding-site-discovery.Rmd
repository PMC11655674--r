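---
title: "Discovering a LuxR-family binding site: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering a LuxR-family binding site: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmotif)
```

## The problem

Quorum-sensing LuxR-family regulators bind degenerate, often palindromic DNA
sites that are notoriously hard to predict. `qsmotif` implements a
desk-scale, fully seeded version of the comparative strategy commonly used
for bacterial transcription factors:

1. take the genes differentially expressed (DE) when the regulator's
   pathway is perturbed;
2. remove genes already explained by a known downstream regulon;
3. collapse the remainder into transcriptional units (operons) and extract
   one regulatory region per unit;
4. obtain the promoters of the regulator's orthologs across related species
   by reciprocal best hits (RBH), and learn a position weight matrix (PWM)
   from them;
5. scan the candidate regions with that PWM at an exact p-value cutoff and
   summarize the (frequently strand-paired) hits.

Every stage consumes and produces standard formats (TSV, FASTA, GFF3, BED,
MEME minimal), and a synthetic-data module generates inputs with known
ground truth so that the whole pipeline is testable offline.

## Models and conventions

### Coordinates and sequence algebra

All coordinates are 0-based half-open internally; GFF3 input is converted
from 1-based inclusive on read. Sequences are upper-cased on load. The
15-symbol IUPAC alphabet is supported throughout: `revcomp()` uses the full
complement table (so the 22-bp degenerate consensus
`RACMTGTCYWWWWRGACAKGTY` is its own reverse complement - the algebraic
signature of a palindromic site), and `match_pattern()` does per-position
base-set matching. A literal `N` in *sequence* only matches a pattern `N`
by default ("strict" mode): this prevents assembly gaps from producing
spurious planted-site matches; a permissive mode is a flag.

### Gene-set construction

* **DE filter** (`filter_de`): |log2FC| >= 2 and adjusted p <= 0.01, both
  inclusive as printed. Records with missing `padj` are dropped with a
  warning rather than imputed - this matches what DE tools emit for
  independent-filtering casualties.
* **Regulon subtraction** (`subtract_regulon`): exact set difference,
  preserving order, reporting the removed count.
* **Operons** (`call_operons`): consecutive same-contig, same-strand genes
  with intergenic gap strictly below 50 bp chain transitively. "Closer than
  50 bp" is read literally as `< 50`. Overlapping genes count as gap 0 and
  are flagged. The 5'-most gene of each unit is its leader.
* **Promoters** (`extract_promoters`): 300 bp upstream + 10 bp downstream
  of the leader's start codon, reverse-complemented for minus-strand
  leaders so the sequence always reads 5'->3' into the coding start. The
  same window is used for PWM-building ortholog promoters and for the
  scanned candidate regions; the source material specifies it only for the
  former, so the shared default is a declared package convention,
  configurable per call. Windows clipped at contig edges are flagged;
  circular-contig wraparound is available behind a flag but off by default.
* **Domain classifier** (`classify_domains`): LuxR requires an
  autoinducer-binding domain score >= 35; a GerE-type HTH score >= 20
  separates full receptors from truncated (anti-activator-like) ones; a
  synthase domain score >= 50 defines LuxI. The classifier is a pure
  function of the scores; dual-family qualifiers keep the LuxR label and
  are flagged.

### Orthology

`align_pair` is a Gotoh affine-gap local aligner (compiled) with BLOSUM62
and BLAST-style gap costs: a gap of length *k* costs `open + k * extend`,
defaults 11/1. Identity is matches over aligned columns *including*
internal gaps; coverage is the aligned span over each sequence's length.
`reciprocal_best_hits` requires mutual top scores plus identity >= 0.35 and
coverage >= 0.70 **in both directions** - the stricter symmetric reading of
a directionless published threshold. Ranking is by raw score (RBH needs
ranks, not E-values, at this scale); ties break lexicographically and are
flagged.

### Motif discovery: ZOOPS EM

`discover_motif` fits the classic zero-or-one-occurrence-per-sequence
model: each sequence carries a site of width `w` (default 22) with
probability `q`, at a latent position and strand uniform over candidate
windows; the rest of the sequence is 0-order background (estimated from
the input by default). The M-step smooths counts with a background-weighted
pseudocount, total mass `4 * alpha` per column (`alpha = 0.25`).

Two design points matter in practice:

* **Seeding and order invariance.** Each restart initializes the matrix
  from one observed w-mer drawn from the *sorted pool* of all w-mers, so
  the fit is invariant to the order of the input sequences at a fixed seed.
* **Register refinement.** Plain ZOOPS EM reliably finds the planted signal
  but often converges a few columns off register (we measured edit
  distances of 6-12 to the planted word at otherwise perfect occupancy).
  The winning restart is therefore refined by the standard column-shift
  move: the matrix is shifted by +-1..3 columns (refilled with background)
  and EM rerun, keeping any likelihood improvement. With this, recovery of
  an exactly planted 22-mer was exact in 10/10 test seeds.

Occupancy is reported as the number of sequences whose posterior
probability of carrying a site is at least 0.5 - a declared threshold
chosen to mirror "present in *k* of *n* sequences" reporting. Because both
strands are searched, the model is identified only up to reverse
complement; recovery tests compare consensus strings up to `revcomp`.
`palindrome_constraint = TRUE` averages the matrix with its reverse
complement each M-step, which forces a revcomp-invariant consensus.

### Motif significance

`motif_significance` reports the posterior-weighted total log-likelihood
ratio of sites versus background, and an E-value-like quantity: the number
of candidate (position, strand) start configurations times a normal upper
tail fitted to Monte-Carlo null replicates. Two nulls are offered:

* `"fixed"` (default): null datasets are scored with the trained model.
  Fast, and correctly separates a planted motif (E << 1e-6) from nothing -
  but *anti-conservative for a model trained on pure background*, because
  training maximizes the observed statistic while the null draws are not
  maximized. We measured z-scores near 12 for background-trained models.
* `"refit"`: the identical discovery is rerun on every null dataset. This
  is the calibrated null (background-trained models score E >> 0.1) at a
  much higher cost; a few dozen replicates suffice because only the bulk of
  the null matters for an insignificance call.

The external motif tool's printed E-value definition is not reproduced;
this package's E-value is an internally consistent, seeded approximation
and should not be compared across tools.

### Scanning with exact p-values

`score_distribution` discretizes the log2-odds matrix to a grid of step
`eps` (default 1e-3, round-to-nearest per cell, so binned and real word
scores differ by at most `w * eps / 2`) and convolves the four per-position
outcomes under the background, yielding the *exact* distribution of the
binned score of a background word. `scan_region` scores words with the same
binned matrix, so each hit's p-value is exactly the tail probability of its
binned score; `pvalue()` on an arbitrary real score uses the floor bin,
which can only over-report (conservative). The minus strand is scanned with
the reverse-complemented matrix and reported at forward coordinates;
windows containing `N` are skipped; overlapping hits are all reported
because multiple and strand-paired hits per region are biologically
expected for palindromic sites. `aggregate_hits` collapses +/- hits at the
same forward offset into one palindromic-pair site and ranks regions by
best p-value.

## The synthetic world

The generators emulate the statistical structure the analysis assumes,
with defaults chosen once to mirror the study system:

* `gen_de_table(4000, 381, 200)`: ~4000 genes is a typical
  alphaproteobacterial genome; 381 DE genes with a 200-gene overlap against
  a 546-gene prior regulon reproduces the documented set arithmetic
  (381 - 200 = 181). DE log2FCs are `sign * (2 + Exp(1))`, non-DE values
  Normal(0, 0.5) truncated to (-2, 2); any sub/supra-threshold law would
  do, these are declared for reproducibility.
* `gen_genome`: fixed gene length (900 bp default) with controllable gap
  and strand laws - the pipeline is sensitive to gaps and strands, not to
  length variation, so length is not randomized.
* `plant_sites`: background GC 0.69 (a high-GC genome); occupancy 18/24
  mirrors the documented ortholog-promoter yield. Per the module contract
  sites are Bernoulli-planted per region; the `n_sites` argument plants an
  exact count, which the acceptance tests use because their criterion is
  stated for exactly 18 of 24 regions.
* `gen_ortholog_family`: i.i.d. substitutions (uniform over the three
  alternatives) at a stated rate outside conserved intervals - a neutral
  model with no indels, rate heterogeneity, or phylogenetic correlation.
* `build_artificial_promoter`: a -35/-10 promoter with a binding site in
  the spacer. Spacer pads default to 9/8 bp so the -35/-10 distance is a
  canonical 17 bp plus the 15-bp inserted site; the real construct's
  spacing is known only graphically, so coordinates are emitted, never
  asserted.

What a green test does *not* establish: performance on real promoters with
heterogeneous composition, repeats, overlapping signals, or indel-diverged
ortholog families; robustness of RBH at genome scale (the aligner is dense
and quadratic, intended for desk-scale protein sets); or agreement with any
specific external tool's scores or E-values.

## Numerical choices and degenerate inputs

* Consensus rule: per column, the candidate set is all bases with frequency
  >= 0.25; its IUPAC symbol is used when the set carries >= 75% of the
  column mass, otherwise `N`. (A "smallest qualifying subset" rule would
  call a uniform column `B`-like; the all-qualifying-bases reading calls it
  `N`, which is the behavior users expect.)
* EM stops when the absolute log-likelihood change falls below `1e-5`
  (default) or at 200 iterations; the likelihood is reported relative to
  the pure-background model, so the additive constant cancels. The M-step
  pseudocount makes EM a MAP procedure; the observed-likelihood trace is
  still monotone to numerical tolerance and is asserted in tests.
* `q` is clamped to [1e-4, 1 - 1e-4]; LR exponents are capped at 700 to
  avoid overflow (double range).
* The score-distribution DP refuses axes beyond `max_bins = 2e7` and
  suggests a larger `eps`.
* Degenerate inputs error early with names: empty proteomes warn, missing
  leader genes name their operon, too-short sequences name themselves.

## Reproducibility

Every stochastic function takes an explicit integer seed and touches the
global RNG only through `set.seed` at entry; identical seeds give
bit-identical outputs, including across sequence reorderings in
`discover_motif`. The pipeline writes its full configuration into both the
log and the JSON summary.
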