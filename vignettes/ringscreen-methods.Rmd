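---
title: "Methods: RING-domain discovery, classification and stress screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RING-domain discovery, classification and stress screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringscreen)
```

`ringscreen` implements a survey pipeline for RING-finger E3 ubiquitin
ligases in plant proteomes. This vignette explains the underlying
models and procedures, the parameters that matter, the synthetic-data
design that makes the pipeline testable, and the choices made where the
design was genuinely open.

## The octet model of the RING domain

The RING domain binds two zinc ions in a cross-brace arrangement through
eight metal-ligand residues, M1 to M8, which are cysteines except at
positions 4 and 5 where histidine also occurs. `ringscreen` models a
domain as an *octet*: eight ligand positions plus the seven spacer
lengths s1..s7 (residues strictly between consecutive ligands). A
grammar (`octet_grammar()`) fixes the allowed residue set per position
and an inclusive integer interval per spacer.

The default grammar follows the canonical RING consensus:
s1 = 2, s2 = 9..39, s3 = 1..3, s4 = 2..3, s5 = 2, s6 = 4..48,
s7 = 1..6, with M1, M2, M3, M6, M7, M8 = Cys and M4, M5 in {Cys, His}.
Published family surveys rarely print explicit spacer bounds, so these
are literature-canonical values and every one of them can be overridden
in the run configuration. The last spacer is deliberately wide: the
spacing between M7 and M8 distinguishes RING subtypes and is therefore
judged by the classifier, not clipped away by the scanner. An `X`
(unknown residue) never satisfies a ligand position: an unconfirmed
residue should not create a domain call.

### Scanning and redundancy resolution

`scan_octets()` enumerates *every* octet placement compatible with the
grammar, growing partial placements position by position over
precomputed candidate indices. The test suite holds this enumeration
identical to a naive brute-force enumerator on random sequences, and a
monotonicity property (widening a spacer interval never removes a raw
match) guards the windowing logic.

Raw placements overlap heavily — a single physical domain can admit
dozens of octet placements. Resolution is deterministic and purely
rule-based:

1. among placements sharing M1, keep the one with the smallest total
   spacer sum (ties: lexicographically smallest position tuple);
2. among placements with intersecting spans, keep the leftmost-starting
   (then smallest spacer sum), greedily left to right.

The compact-first rule prefers the tightest reading of a region, and
the greedy left-to-right pass lets truly disjoint domains in one
protein coexist (multi-RING proteins are reported with one match per
domain). Ties cannot survive all three criteria, so output is
byte-stable across runs and platforms.

`filter_by_hits()` optionally restricts scanning to HMMER domain-hit
envelopes plus a flank (default 25 residues), mirroring pipelines that
pre-screen with profile HMMs; coordinates are always mapped back to the
full sequence, and overlapping windows are merged first so no region is
scanned twice.

## Subtype signatures

Classification uses only (M4, M5, s7), per the field's naming of RING
subtypes: RING-H2 = (H, H); RING-HCa = (H, C) with s7 = 2;
RING-HCb = (H, C) with s7 = 4; RING-C2 = (C, C); RING-v = (C, H). The
source literature distinguishes HCa from HCb by "two and four amino
acids" between ligands 7 and 8 — read here as HCa = 2 and HCb = 4, the
one open reading documented rather than guessed further. RING-G is
named in family surveys but nowhere structurally defined; its default
row is a provisional catch-all for the remaining (H, C) spacings and is
meant to be replaced via configuration should a definition emerge.

The table is an ordered, first-match-wins rule list, so a user-edited
table with overlapping rows still classifies deterministically (overlap
additionally triggers a warning, detected by exhaustive enumeration
over (M4, M5, s7)). Under the default grammar the six rows are
exhaustive and pairwise disjoint, which the tests verify by evaluating
all residue combinations against all admissible s7 values. Because one
protein can carry several domains, family summaries report both
domain-level and protein-level counts.

## Redundancy collapse

Proteome releases carry near-identical entries (alternative gene models,
assembly artifacts) that manual surveys remove by hand. `ringscreen`
replaces that with a two-phase deterministic procedure
(`collapse_redundant()`): exact sequence duplicates collapse to the
lexicographically smallest id; then pairs with global-alignment identity
>= 0.99 and mutual coverage >= 0.9 are single-linked and each cluster
collapses to its longest member (ties: smallest id). The thresholds are
deliberately conservative — only near-identical entries are removed —
and both are configurable. The procedure is idempotent and
order-independent, and conservation (|kept| + |removed| = |input|) is
asserted by the pipeline.

Identity is computed by Needleman–Wunsch with match +1, mismatch 0 and
linear gap −1 (end gaps penalized), identity = identical pairs /
alignment length. Under that scoring, co-optimal alignments with
different identity exist; to make the statistic well-defined the DP
maximizes (score, identical pairs, aligned columns) lexicographically —
valid because all three objectives are additive along an alignment
path. The core is ~50 lines of C++ (Rcpp); an independent plain-R DP
oracle checks it on random pairs. All-vs-all comparison is exact: the
only pruning is a provable length-ratio screen (identity and mutual
coverage are each bounded above by min(len)/max(len), so pairs below
`max(threshold, coverage)` in length ratio cannot qualify).

## Stress screen and Venn decomposition

Expression input is a gene x stress x timepoint table of control and
treatment values in abstract non-negative units (public expression
archives variously serve FPKM or TPM; the screen is unit-agnostic
because it uses only ratios). For each cell the screen computes
`log2((treatment + p) / (control + p))` with pseudocount p = 0.1 for
robustness at zero expression. A gene is *responsive* to a stress when
any timepoint reaches twofold: |log2 ratio| >= 1, boundary inclusive
("twice as much" is read as reaching twofold). Direction is `up`/`down`
when all qualifying timepoints agree in sign, `mixed` otherwise.
Raising the threshold can only shrink responsive sets (tested as a
property).

`venn_decompose()` splits the union of responsive genes into
exact-membership cells — one per non-empty subset of the stress set
(2^k − 1 cells, k <= 6; the survey design uses four: cold, salt,
drought, and methyl jasmonate as a proxy for biotic stress). Cells are
disjoint and sum to the union; each per-stress total equals the sum of
cells containing that stress, both enforced at run time. The screen's
default gene set is the RING-H2 members found upstream — the family's
dominant subtype and the set the source survey screened — with a
configuration switch to screen all genes, since family-wide screens are
equally common; the ambiguity is surfaced as an option rather than
resolved silently.

No differential-expression statistics are attempted: the screened
archive data carry no replicates, so the twofold rule is a selection
heuristic, not a test — which is also why the synthetic margins below
matter for interpreting recovery results.

## qPCR quantification

`delta_delta_ct()` implements classic 2^-ddCt with amplification
efficiency fixed at 2 and no efficiency correction (none is available
without standard curves). Per replicate, dCt = Ct(target) −
Ct(housekeeping), paired within a well by (sample, replicate); per
sample, replicates aggregate as the mean of technical replicates within
each biological replicate, then the mean across biological replicates
(labels `b<i>.t<j>`; a pooled mean is available and identical for
balanced designs). ddCt is taken against the untreated calibrator
sample, whose fold is exactly 1 for any input. Dispersion is reported
as the standard deviation of per-replicate dCt and labeled as such.
Invariance to adding a constant to all of a sample's Ct values is a
tested property. `summarize_timecourse()` reports each gene's maximum
fold and its timepoint, ties resolved to the earliest timepoint.

## Synthetic data: what it emulates, and what it does not

The generators produce the three pipeline inputs with planted truth.

**Proteome** (`generate_proteome()`): each planted protein embeds one
grammar-conformant motif of a requested subtype between background
flanks; decoys are either shuffled background or *near-misses* — a real
motif violating exactly one constraint (one ligand mutated, or one
spacer pushed just outside its interval), the adversarial case for a
scanner. In the default `"clean"` background, flank, decoy and spacer
residues are drawn uniformly from the 18 non-Cys/His letters, which
makes accidental octets impossible by construction; a `"realistic"`
mode uses all 20 letters with rejection sampling, re-drawing flanks
until the scanner finds exactly the planted truth. Every record is
verified with the scanner itself before it is emitted.

**Expression** (`generate_expression()`): memberships are planted per
exact-membership Venn cell. Member (gene, stress) pairs get one
timepoint with |log2 effect| in [1.5, 3.0] and random sign; every other
effect stays within +/-0.3. Noise on the log2 scale is Gaussian with
sd 0.1, *truncated at 3.9 sd*: the generator's contract promises that
noise never flips a planted call, and untruncated tails would break
that promise with small probability. Both margins
(1.5 − 1 and 1 − 0.3 around the twofold threshold) must be at least
4 x noise sd or the generator refuses to run. Control levels are drawn
per (gene, stress) from 5–50 units so the pseudocount's shrinkage
cannot push a marginal member below threshold.

**Ct tables** (`generate_ct()`): per well, the housekeeping Ct is the
baseline (20 cycles) plus noise, and the target Ct is that same well's
housekeeping Ct plus the calibrator dCt (3 cycles) minus log2(planted
fold) plus noise — so per-replicate dCt noise has the per-well sd
(default 0.05 cycles), and recovered folds carry a relative error of
about ln(2) x sd x sqrt(2/9) for a 3 x 3 design.

What the generators do *not* emulate: real sequence composition and
homology structure (planted flanks are i.i.d. background, so dedup on
synthetic data only exercises injected duplicates), expression
correlation across timepoints and stresses, amplification-efficiency
variation, and any read-level RNA-seq structure. Passing the planted
recovery suite therefore demonstrates the pipeline's correctness, not
the biological sensitivity/specificity of the default grammar on real
proteomes.

**The study-scale preset** (`inst/extdata/preset_paper.yaml`,
`paper_preset()`) fixes the survey-scale configuration: 335 planted
proteins (214 H2 / 104 HCa / 3 HCb / 7 C2 / 6 v / 1 G) with 500 decoys;
a 214-gene expression design whose cells give per-stress totals
128/134/121/82, all-four intersection 53, exclusives 26/5/0/0; and
planted folds including 3.28 at salt-12h. Published surveys print only
marginal counts, so the preset's interior Venn cells and the HCa/C2/v
split are free parameters chosen once to satisfy every printed marginal
exactly; the preset file marks them as such.

## Numerical and degenerate-input choices

- Coordinates are 1-based inclusive everywhere in user-facing output.
- Tabular IO is tab-separated UTF-8 with mandatory headers; readers
  validate rather than coerce (duplicate keys, negative expression,
  non-finite Ct, missing housekeeping rows are errors, not warnings).
- FASTA: one trailing `*` (translated stop) is stripped; `*` elsewhere
  and letters outside the 20 standard residues + `X` are errors;
  empty sequences and duplicate ids are errors.
- Empty inputs flow through: an empty FASTA yields an all-zero report
  and exit success; an empty match set yields an all-zero family
  summary; scanning with no usable domain hits returns an empty result
  and logs it.
- The twofold boundary is inclusive; ties in timecourse summaries go to
  the earliest timepoint; dedup ties go to the longest sequence, then
  the smallest id.
- All randomness is confined to the generators, which take explicit
  seeds, restore the caller's RNG state, and are byte-deterministic
  given a seed.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on synthetic data at
the scale of the study design they emulate: an 835-protein proteome
(335 planted + 500 decoys), a 214-gene x 4-stress x 3-4-timepoint
expression matrix, and 3 x 3-replicate Ct tables; oracle-equivalence
suites use 1,000 random sequences up to 200 residues (scanner), random
membership matrices up to 64 genes (Venn), and random pairs up to 30
residues (alignment DP). The full pipeline on the study-scale preset
runs in well under a minute on one CPU.

## Known limitations

- The scanner is exhaustive for its grammar but the default grammar is
  a consensus: genuinely atypical RING domains (and the S/T, D, mH2,
  mHC variants some surveys describe) are out of scope by design.
- RING-G's signature is provisional (see above).
- Dedup has no isoform/locus awareness — without gene models it cannot
  distinguish alternative transcripts from assembly duplicates.
- The stress screen has no statistical model; it reproduces a selection
  rule, and its counts inherit whatever normalization the input
  expression values carry.
- `pairwise_identity()` is quadratic per pair; the pipeline's
  length-ratio screen keeps family-scale dedup fast, but all-vs-all
  identity on whole proteomes is not the intended use.
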