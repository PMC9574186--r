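---
title: "Methods: C2H2 zinc-finger family characterization with zfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: C2H2 zinc-finger family characterization with zfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`zfkit` characterizes plant C2H2 zinc-finger protein (C2H2-ZFP)
families: it detects the zinc-finger domains, types them by the
degradation of the plant-specific QALGGH motif and the spacing of the
zinc ligands, derives gene structure, duplication and promoter
cis-element context, estimates selective pressure on duplicate pairs,
and analyzes five-stage dehydration–rehydration expression responses.
This vignette records the model, its assumptions, the tunable
parameters, and the numerical choices — particularly where the design
was genuinely open.

## 1. Finger detection

A C2H2 zinc finger is modeled as the scaffold

```
C - X(c1c2) - C - X(c2h1) - H [- X(h1h2) - H]
```

with `c1c2` in 2–4, `c2h1` in `min_spacer`–`max_spacer` (defaults 8 and
25, bracketing the family's 25–30 aa domain span), and `h1h2` in 3–5
when the second His is present. A match without the second His — no His
at all 3–5 residues after H1 — is a D-type candidate. Two deliberate
relaxations:

* The conserved internal P and L of the full consensus
  `C-X2~4-C-X3-P-X5-L-X2-H-X3-H` are **not** required. Degenerate (M-,
  Z-, D-type) fingers violate them, and the family definition must
  admit those fingers.
* `X` in the input is tolerated inside spacers but never accepted as a
  ligand.

**Overlap resolution.** All grammar-conformant parses are enumerated;
matches are then chosen leftmost-first and greedily (scanning resumes
after the accepted match). Competing parses at the same start are
ranked by

1. presence of the second His — complete fingers beat H2-less
   candidates;
2. Cys2–His1 spacer closest to the canonical 12, ties toward the
   smaller spacer;
3. smaller Cys1–Cys2 spacer, then smaller His1–His2 spacer.

Rule 1 is essential, not cosmetic: a Z2 finger such as
`C-X2-C-X9-H-X3-H` also admits an H2-less parse that treats its second
His as H1 with spacer 13; ranking by spacer alone would misread every
short-spacer finger as D-type. Rule 2 maximizes canonical-finger calls
and makes the scan deterministic. The scanner is property-tested for
exact agreement with a brute-force enumerator applying the same written
rules over all index tuples.

## 2. Classification

Each detected finger receives exactly one label from a total decision
tree:

1. second His absent → `D`;
2. Cys2–His1 spacer ≠ 12 → `Z1` if > 12, `Z2` if < 12;
3. spacer = 12 → Hamming distance of the six residues ending at H1 to
   `QALGGH`: 0 → `Q`, d in 1–5 → `Md`.

Because position 6 of that six-mer is H1 itself, any spacer-12 finger
has distance ≤ 5, so step 3 is exhaustive; conversely a spacer-12
finger is never labelled Z. An exact `QALGGH` at a spacer other than 12
classifies by the spacing rule (Z) — spacing takes precedence — and is
flagged in `qalggh_offspacing` for audit, since such fingers are rare
and a curator may wish to inspect them.

**Pure vs mixed proteins.** M1–M5 and Z1/Z2 collapse to coarse M and Z;
a protein is `mixed` when it carries ≥ 2 distinct coarse types. Whether
mixedness should count M subtypes as distinct is genuinely open; we
chose the coarse Q/M/Z/D granularity (so an M1 + M3 protein is
`pure:M`) because the type system itself is defined at that granularity.
The fine labels remain in the output, so the other convention is one
`table()` away.

## 3. Physicochemistry

Molecular weight uses average (not monoisotopic) residue masses plus
one water, matching ProtParam conventions; `G` alone is 75.07 Da. The
isoelectric point solves `charge(pH) = 0` by bisection on \[0, 14\]
(tolerance 1e-4 on the charge), where the net charge is the
Henderson–Hasselbalch sum over the termini and the D, E, C, Y, K, R, H
side chains with a Bjellqvist-style pKa table; the charge function is
strictly decreasing in pH, so the root is unique. GRAVY is the mean
Kyte–Doolittle hydropathy, bounded in \[−4.5, 4.5\]. The ambiguous
residue `X` contributes the mean residue mass, zero hydropathy and no
charge, and is flagged. The mass, pKa and hydropathy tables ship in the
package source and the pKa set is an argument.

## 4. Genome context

Coordinates are GFF3 throughout: 1-based, inclusive. One gene model is
kept per gene — the mRNA with a truthy `canonical`/`primary` attribute
when present, otherwise the lowest-sorting mRNA ID (deterministic).
Intron count is exon count − 1.

**Promoters** are anchored on the translation start (first CDS base),
not the transcription start: plus strand
`[translation_start − 2000, translation_start − 1]`, minus strand the
reverse complement of `[translation_start + 1, translation_start +
2000]`, truncated and flagged at contig edges.

**Duplicate pairs** combine sequence similarity with physical position:
all-vs-all Needleman–Wunsch protein alignment (identity scoring), pairs
kept at identity ≥ 0.70 over ≥ 0.70 coverage of the shorter sequence. A
pair is *tandem* when same-chromosome with ≤ 10 intervening family
genes and ≤ 100 kb apart, else a (segmental) *duplicate*; tandem arrays
are connected components of the tandem relation. The similarity and
proximity thresholds are package defaults — the literature rarely
prints them — and all are arguments.

## 5. Cis-acting elements

The default dictionary ships the printed strings: the ABRE core `ACGTG`
and the composites `CGCACGTGTC`, `CGTACGTGCA`, `GCAACGTGTC`; the G-box
`CACGTG`; the MBS drought-inducibility motif `CAACTG`; the
MeJA-responsive `CGTCA`. DRE, TC-rich, LTR and auxin (TGA-box) classes
have no universal published strings and are therefore config-supplied,
empty by default. Scanning counts **overlapping** occurrences
(shift-by-one) of the motif and, separately, of its reverse complement
on the same strand; IUPAC codes in motifs expand to character classes.
Two consequences are documented rather than hidden: palindromic motifs
(e.g. `CACGTG`) count once in each strand column, and a composite motif
containing the core (every `CACGTG` contains one `ACGTG`) contributes
to the core's count. Both columns are reported so users can de-duplicate
under their own convention.

## 6. Molecular evolution

**Alignment.** Needleman–Wunsch with linear gap penalty (defaults
+1/−1/−2), via `Biostrings::pairwiseAlignment`; scores are
property-tested against exhaustive enumeration at small lengths. Codon
alignment threads the protein alignment back onto codons; columns with
a gap or ambiguous base are dropped and counted, and internal stop
codons are an error naming the sequence and codon.

**NG86 Ka/Ks.** Sites per codon: each of the 9 single-base changes
contributes 1/3 of a synonymous or nonsynonymous site. Changes creating
a stop codon contribute to **neither** class. This is the one place we
deviate from the most common convention (stops counted as
nonsynonymous): a coding sequence cannot substitute into a stop, so
counting stop changes as nonsynonymous opportunity deflates Ka — under
a neutral stop-rejecting simulation the conventional count is visibly
biased, while the mutable-space count is calibrated. Differences per
codon pair are averaged over all substitution pathways, excluding
pathways through stops and renormalizing (uniform over all pathways in
the rare case every pathway is blocked). Proportions are Jukes–Cantor
corrected, `d = −(3/4)·ln(1 − 4p/3)`, with `p ≥ 3/4` a hard "saturated"
error. Modes: ratio < 1 purifying, within 1e-9 of 1 neutral, > 1
positive; `Ks = 0` leaves the ratio undefined. NG86 was chosen because
the method behind published family tables is typically an undocumented
toolbox default; numeric deltas against model-based estimators (GY94,
YN00) are expected and the estimator is clearly named in all output.

Note on calibration checks: the mean of per-pair ratios is inflated by
Jensen's inequality (≈ +CV(Ks)²), so neutrality checks in the test
suite use the pooled estimate `mean(Ka)/mean(Ks)` with a delta-method
CI, equivalently the paired `Ka − Ks` difference.

**NJ tree.** Saitou–Nei neighbor joining (`ape::nj`) on a validated
symmetric distance matrix; negative branch lengths are clamped to zero
and counted. Additive matrices are reproduced exactly (tested at 3, 4
and 5 taxa against hand-computed path distances).

## 7. Dehydration–rehydration expression

Stages are fixed as HD (hydrated control), MDH (moderate dehydration),
SDH (severe/deep dehydration), PRE (partial rehydration), FRE (full
rehydration), three replicates each.

**DEG rule.** Contrasts are each treatment stage vs HD (4 contrasts). A
gene is a DEG when, for at least one contrast, |log2FC| ≥ 1 **and** all
three per-method significance values are < 0.05 at the same time. Genes
missing from a method's table are non-significant there (with a
warning). The rule makes the DEG set a subset of each single method's
set and monotone under threshold relaxation; both properties are
tested.

**Standardization.** Stage means are taken to log2 (the scale
time-course clustering conventionally runs on; pseudocount 0 by
default, so undetected genes should be filtered or given a pseudocount)
and z-scored per gene across the five stages; zero-variance and
non-finite genes are excluded and reported.

**Fuzzy c-means.** Standard FCM on Euclidean distance, fuzzifier
`m = 2` (the common default; the upstream choice is undocumented),
tolerance 1e-6 on the objective decrease, ≤ 1000 iterations. Centroids
are seeded from the data with D²-weighted (kmeans++-style) sampling
driven by `seed`: near-duplicate profiles then cannot absorb two seeds,
which makes noise-free worlds recover exactly and noisy worlds robust.
The objective is non-increasing by construction and asserted in tests.
Cluster labels are canonicalized by the total-distance-minimizing
assignment (exhaustive over permutations for c ≤ 8) of centroids to six
fixed template profiles, so "pattern k" means the same thing across
runs:

| pattern | shape (HD, MDH, SDH, PRE, FRE) | reading |
|---|---|---|
| 1 | 1.0, 0.1, 0.0, 0.1, 1.0 | high at both ends, suppressed during dehydration |
| 2 | 0.0, 0.5, 1.0, 0.4, 0.1 | peak at severe dehydration (dehydration-induced) |
| 3 | 0.2, 0.0, 0.0, 0.3, 1.0 | peak at full rehydration |
| 4 | 0.2, 1.0, 0.4, 0.1, 0.0 | peak at moderate dehydration (early response) |
| 5 | 1.0, 0.6, 0.3, 0.1, 0.0 | highest in the hydrated control, declining |
| 6 | 0.0, 0.1, 0.3, 1.0, 0.4 | peak at partial rehydration (rehydration-induced) |

The peak placements follow the published qualitative descriptions of
the six patterns; the exact values are this package's choice, fixed
once, with patterns 1/3/5 given distinct end-weighting so the six
templates are well separated after z-scoring.

**Integration.** One row per DEG joins species, pattern, phylogenetic
group (an *external input* — tree-based group assignment is out of
scope), coarse finger types, promoter ABRE/DRE/MBS counts, per-contrast
directions and per-stage log2(FPKM + 1) display values; unmappable DEGs
go to a reject report.

## 8. The synthetic world

Generators emit data **plus a truth table**, and self-verify by running
the consuming stage on their own output before returning.

* **Proteomes.** Planted fingers are exact instances of their type's
  pattern. Linkers (10–15 aa) and flanks (5–10 aa) draw from the 18
  residues excluding C and H, so ligand positions are unambiguous and
  the scanner's round trip is exact by construction. A manifest fraction
  of proteins receives a coiled-coil entry in the additional-domain
  annotation table (domain *annotations* stand in for external domain
  scans — the accessory domains are not encoded in sequence).
* **Genomes.** Each gene is a 2000-nt promoter followed by its CDS over
  1–4 exons, alternating strands, with 200-nt spacers. Promoter
  backgrounds draw from {A, C, T} — every shipped motif and its reverse
  complement contains a G — and planted motifs are wrapped in 5-nt T
  buffers; the assembled promoter is re-scanned and must show exactly
  the expected counts (plants plus substring containments among the
  planted strings), else it is resampled. Tandem arrays are adjacent
  genes with ~2% codon substitution from a shared CDS.
* **Duplicate pairs.** Codon-wise substitution from a stop-free common
  ancestor: per codon, one substitution opportunity at a random
  position shared by the two descendants; proposals are accepted with
  probability `syn_rate` or `nonsyn_rate` by their effect, and stop
  codons are always rejected. Sharing the position keeps codon pairs at
  most one base apart, so pathway averaging is exact and
  `nonsyn_rate = 0` gives Ka = 0 exactly at any rate — with independent
  per-site substitution, rare two-position synonymous differences in
  six-box codons (Leu/Arg/Ser) would make NG86 report spurious
  nonsynonymous pathway steps. Defaults used in tests: neutral
  0.09/0.09 (~6% site divergence, well inside the Jukes–Cantor domain);
  purifying 0.45/0.045 (10× suppression).
* **Expression.** DEG genes follow their template with stage means
  `base · 2^(3 · template)` (lognormal baselines, median 20 FPKM) and
  lognormal replicate noise of log-sd 0.2 — a typical between-replicate
  spread for stage-mean FPKM with three replicates; non-DEGs are flat.
  Significance columns are generated directly (the upstream DE methods
  are consumed as tables, not reimplemented): true DEGs get all three
  significances < 0.05 on contrasts whose planted and realized fold
  change clears 2×, non-DEGs always fail the third method. The
  generator re-applies the DEG rule before returning and regenerates a
  gene's noise if a planted DEG fails the fold-change bar (planted
  qualifying effects are ≥ 2.4 log2 units, so retries are ~8σ events).

**What the synthetic world does not emulate** — and therefore what a
green test does not establish: realistic genome composition or motif
background frequencies (real promoters contain incidental motif hits;
the generators build motif-free backgrounds so truth is exact); decoy
fingers and edge-degenerate domains (planted fingers are exact type
instances separated by ligand-free linkers); read-level RNA-seq noise,
library-size effects, or the internals of the three DE methods;
accessory protein domains in sequence. Green round-trip tests establish
that each stage implements its stated rule exactly, not that the rules
themselves would reproduce a published census on real genome releases —
those depend on database versions, isoform annotations and external
domain scanners.

## 9. Known limitations

* NG86 with Jukes–Cantor correction ignores transition/transversion
  bias and codon frequencies; ratios on real duplicate pairs will
  differ from model-based estimators, particularly at high divergence.
* The scanner's spacer bounds (8–25) exclude exotic fingers with very
  long inserts; widen `max_spacer` to admit them (at the cost of more
  ambiguous parses).
* Fuzzy c-means with template anchoring assumes six patterns; a
  different `centers` disables template canonicalization unless a
  matching template matrix is supplied.
* The pI bisection assumes the shipped pKa set; heavily modified or
  very short peptides are outside its calibration.
* Group (clade) assignments are consumed as input; the package builds
  only desk-scale NJ trees, not the bootstrapped ML phylogenies used
  for formal group definitions.
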