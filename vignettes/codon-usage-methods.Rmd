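---
title: "Codon usage bias analysis with cubkit: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## The problem

Synonymous codons are not used at random. In a virus genome the observed
usage pattern is the fingerprint of two forces: *mutation pressure* (the
genome-wide nucleotide bias that drifts all codon positions together) and
*natural selection* (translational and structural constraints acting mostly
on the first two codon positions, and host-imposed preferences acting on
the silent third position). `cubkit` packages the standard battery of
statistics used to separate these forces and to quantify how well a viral
gene is adapted to a host's codon usage — the workflow applied to small
DNA viruses such as torque teno sus virus (TTSuV), whose ~1.9 kb capsid
ORF is the bundled motivating example.

Everything operates on in-frame CDS. The genetic code is fixed to the
standard nuclear code; Met (ATG), Trp (TGG) and the three stop codons are
excluded from all synonymous statistics, leaving **59 sense codons in 18
synonymous families** (nine 2-fold, the 3-fold Ile family, five 4-fold,
three 6-fold). This family structure is the single shared backbone of the
package — RSCU vectors, ENC degeneracy classes, CAI/RCDI weights and PCA
axes all derive from it.

## Statistics and their assumptions

### Composition

Silent-site quantities follow the CodonW conventions: A3s/T3s/G3s/C3s and
GC3s are computed over third positions of *synonymous codons only*; GC1 and
GC2 over the first/second positions of that same codon set; GC12 is their
mean. GC fractions are kept in [0, 1] internally (so GC3s can feed the
expected-ENC curve directly) and converted to percentages only for
reporting. Codons containing IUPAC ambiguity codes are excluded from every
count and tallied per sequence — the alternative, imputing fractional
counts, invents data.

### RSCU

`RSCU_i = g_i / (family mean of g)`: 1 means no bias, and each observed
family sums to its size. Zero-count codons get RSCU 0 (no pseudo-counts);
a family with zero total is marked *unobserved* and downstream censuses
refuse to run rather than impute. Representation thresholds are ≥ 1.6
(over-represented) and ≤ 0.6 (under-represented); the inclusive upper
boundary is deliberate, because published reference tables place codons at
exactly 1.60 inside the over-represented set. Preferred-codon ties are
resolved lexicographically for scalar outputs but always reported.

Group-level RSCU can be formed two ways — pooling counts before the ratio,
or averaging per-sequence profiles — and the two differ when sequence
lengths or compositions differ. Both are provided (`pooled_rscu()`,
`mean_rscu()`) and labelled via the `source` attribute; the bundled
reference comparisons use profile means, which reproduce the published
virus×host similarity values.

### ENC and the expected curve

Wright's estimator averages the family homozygosity
`F = (nS − 1)/(n − 1)`, `S = Σ (n_i/n)²` within each degeneracy class:
`ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`. Families with n < 2 are excluded
from their class average; if the lone 3-fold family (Ile) is missing, F̄₃
is imputed as the mean of F̄₂ and F̄₄ (Wright's fallback); a missing 2-, 4-
or 6-fold class makes ENC an explicit error in `enc()` and a flagged `NA`
row in `enc_batch()` (legitimate inputs — e.g. two-family synthetic panels
— would otherwise kill a whole batch). Sampling noise can push the
estimator past the theoretical maximum; such values are capped at 61 and
flagged. The ENC-plot reference curve is the standard
`2 + s + 29/(s² + (1−s)²)`, the expected ENC when codon choice is driven
purely by a silent-site GC content *s*; genes below the curve are under
additional (selective) constraint. The conventional ENC < 35 strong-bias
flag is reported but nothing downstream depends on it.

### Neutrality regression

OLS of GC12 on GC3s across sequences. Under pure mutation pressure all
positions drift together (slope 1); selection on positions 1–2 flattens
the line, so slope×100 is read as the percentage of variation attributable
to mutation pressure and 100×(1−slope) to selection. The fit reports a
two-sided p-value for the slope, its 95% CI, and a confidence band of the
mean response (the band drawn in the usual neutrality plots). No
multiple-testing correction is applied — one planned regression per group
is the design. A perfect or variance-free input errors loudly rather than
returning a meaningless fit.

### CAI, RCDI and SiD

The published analyses this battery mirrors computed CAI and RCDI through
web servers without printing formulas; `cubkit` implements the formulas
those servers document. CAI is Sharp & Li's geometric mean of relative
adaptiveness `w = RSCU/RSCUmax` over all synonymous codon occurrences.
RCDI is Puigbò's `1/N Σ n_i · CiF_gene,i / CiF_host,i` with CiF the
within-amino-acid codon frequency. A useful, test-enforced fact: by
Cauchy–Schwarz RCDI ≥ 1 with equality exactly at host-matched usage, so
RCDI is *not* monotone when starting from a host-optimal-only gene — it is
minimized at the host mix and increases along any path away from it.

SiD is the cosine distance between the two 59-dimensional RSCU vectors:
`R(A,B) = Σ a_i b_i / √(Σ a_i² Σ b_i²)`, `D = (1 − R)/2`. For non-negative
RSCU vectors R ≥ 0, so D effectively lives in [0, 0.5] even though the
index is conventionally described on [0, 1]; the package documents rather
than "fixes" this.

Host references are built from RSCU tables (bundled *Sus scrofa* and
*Sus scrofa domestica* profiles) or Kazusa codon-usage text files. A host
codon with zero usage would send CAI to −∞ on any gene that uses it;
zero entries are floored at half the smallest positive value in their
family — the analogue of granting half an observation, chosen because the
inputs are frequency/RSCU tables without accessible raw totals — with a
loud warning. An all-zero family is an error.

### Dinucleotide odds

`Pxy = f(xy) / (f(x) f(y))` with overlapping all-positions counting over
the CDS as given (codon-bridging pairs included — the default of the
standard desktop tool for this statistic); `mode = "circular"` adds the
wrap-around pair for circular genomes. Calls use the conventional 1.23 /
0.78 thresholds. Batch summaries report the sample SD (n − 1).

### PCA

Covariance PCA (`prcomp`, centered, unscaled) on raw RSCU values: RSCU is
already family-normalized, so per-codon rescaling would distort family
weighting. The historical tool chain for this analysis offered
correspondence analysis under a PCA label; plain PCA is implemented here
and this divergence is the main reason published variance shares are not
expected to reproduce exactly. Axis signs are fixed (largest-|loading|
coordinate positive) so outputs are reproducible; an all-identical input
returns zero coordinates with a warning so batch pipelines survive.

## The synthetic-data generator

`generate_cds()` samples codons i.i.d.: amino acid ~ `aa_weights`
(default: uniform over the 18 families, so every codon participates in the
synonymous statistics; Met/Trp can be opted in), then codon within family ~
`family_codon_weights`. Three weight modes: explicit vectors; a
`gc3_target` mode where, inside each family, GC-ending codons share
probability *t* and AT-ending ones 1 − *t* (every family contains both, so
any target in [0, 1] is feasible and the expected GC3s equals the target
family-by-family); or a symmetric Dirichlet draw with concentration
`bias_concentration` (small = sharply biased usage). Defaults state the
intended world plainly: 630 codons per sequence, the size of the ~1.9 kb
viral capsid ORF the battery targets.

`generate_neutrality_panel()` produces sequences whose (GC3s, GC12) points
scatter around a chosen line. GC12 is steered by an Ala/Lys amino-acid
mixture (GCN contributes GC at positions 1–2, AAR contributes AT) and GC3s
by the third-base choice within both families, making the two coordinates
independently controllable — a deliberately minimal two-family design. Its
limits are worth stating: panels carry no 6-fold family (so ENC is
undefined on them — by design `enc_batch()` flags rather than fails), no
phylogenetic correlation between sequences, no dinucleotide constraints
and no recombination. A green slope-recovery test therefore establishes
that the regression machinery is calibrated for i.i.d. Gaussian-ish
scatter of independent sequences, not that real, phylogenetically
correlated virus panels meet OLS assumptions.

The i.i.d. generator likewise emulates only the multinomial sampling
structure the statistics assume — real coding sequences have amino-acid
autocorrelation, dinucleotide biases and shared ancestry that it does not
reproduce.

## Numerical and interface choices

- **Frames and stops**: strict mode rejects non-multiple-of-3 input;
  `trim_trailing` drops 1–2 trailing bases. A terminal stop codon is
  accepted (complete ORFs end in one) and excluded from statistics; an
  internal stop is a validation error. Invalid FASTA records are reported
  with reasons — either as a batch error naming them or, with
  `on_invalid = "skip"`, as an attached failure table — never silently
  dropped.
- **Determinism**: a fixed generator seed yields byte-identical FASTA;
  `run_report()` writes a `summary.json` that is byte-identical across
  re-runs of the same configuration (timestamps only in the log). TSVs
  print at 3 decimals; JSON keeps full precision.
- **Boundary policy**: representation calls use ≥ 1.6 / ≤ 0.6; RSCU of
  exactly 1 is "neutral".
- **Ties**: argmax ties in preferred-codon extraction are resolved to the
  lexicographically first codon for scalar outputs, flagged in the
  returned table, and warned about in censuses.
- **ENC degenerate inputs**: see above — error in the scalar API, flagged
  NA in the batch API, cap-and-flag above 61.
- **Simulation spec files**: YAML (`yaml::read_yaml`, which also accepts
  JSON), mirroring `generator_spec()` field for field.

## What the tests establish

The test suite verifies every statistic against an independently coded
direct evaluation of its definition (RSCU, ENC, dinucleotide odds, PCA via
`eigen` on the covariance matrix), closed-form toys (CAI 0.75 on a
two-codon Glu gene; F = 0.5 for a 3:1 Lys family; expected ENC 60.5 at
s = 0.5), ground-truth recovery from the generator (GC3 targets, ENC
limits 20/→61, ≥90% CI coverage of a 0.13 neutrality slope over 500
panels), and the bundled-reference quantities (the four virus×host SiD
distances, coincidence/antagonism counts, ending censuses, and the
over-represented codon set). Published *sequence-set-level* numbers — genus
ENC means, neutrality slopes, CAI/RCDI ranges, dinucleotide means, PCA
variance shares — require the full GenBank ORF1 sequence sets and are
deliberately out of scope: `run_report()` will compute them for any
user-supplied FASTA of those accessions, but no test asserts them.

## Known limitations

- Ungapped CDS only; alignment, recombination screening and phylogenetics
  belong to upstream tools.
- Plain PCA, not correspondence analysis (see above).
- SiD on non-negative profiles cannot exceed 0.5.
- The expected-ENC curve and the neutrality slope interpretation are
  heuristics of the field, not fitted models; the package reports them
  as-is.
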