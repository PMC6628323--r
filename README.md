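# cubkit

Codon usage bias analysis for viral coding sequences in R.

`cubkit` implements the full analysis battery that molecular evolution
studies apply to small-virus coding sequences — the kind of workflow used to
dissect how mutation pressure, natural selection and host adaptation shape a
virus such as torque teno sus virus (TTSuV) through its major capsid ORF:

- **Composition** — base content, silent-site third-position content
  (A3s/T3s/G3s/C3s), GC by codon position (GC1, GC2, GC3s, GC12).
- **RSCU** — relative synonymous codon usage
  (RSCU&#8321; = g&#8321; / mean of its family's counts), preferred codons,
  over-/under-representation calls (≥ 1.6 / ≤ 0.6), codon-ending censuses,
  and virus-vs-host coincidence/antagonism comparison over the 18
  synonymous families.
- **ENC** — Wright's effective number of codons
  `ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆` with
  `F = (nS − 1)/(n − 1)`, `S = Σ (nᵢ/n)²`, plus the expected curve
  `ENC* = 2 + s + 29/(s² + (1−s)²)` for ENC-plots (s = GC3s).
- **Neutrality analysis** — OLS of GC12 on GC3s; slope×100 ≈ % mutation
  pressure, remainder natural selection, with slope CI and confidence band.
- **Host adaptation** — CAI (geometric mean of w = RSCU/RSCUmax),
  RCDI (mean within-amino-acid frequency ratio gene/host), and
  SiD (D = (1 − cosine(RSCU_virus, RSCU_host))/2) against host references;
  Kazusa codon-usage tables and bundled *Sus scrofa* /
  *Sus scrofa domestica* references are supported.
- **Dinucleotides** — the 16 odds ratios Pxy = f(xy)/(f(x)f(y)) with
  1.23/0.78 representation thresholds (linear or circular counting).
- **PCA** — covariance PCA over 59-dimensional RSCU vectors with
  deterministic axis signs.
- **Synthetic data** — a generator of in-frame CDS with controllable
  amino-acid usage, per-family codon weights or GC3 target, and a
  neutrality-panel generator with a known GC12~GC3s slope, so every
  statistic has ground-truth-bearing test input.

Bundled fixtures: published 59-codon RSCU profiles of the TTSuV1 and TTSuV2
genera (ORF1 gene sets) and of the two pig hosts
(`inst/extdata/rscu_reference_profiles.tsv`).

## Worked example

```r
library(cubkit)

## virus vs host codon usage, from the bundled reference profiles
p <- builtin_rscu_profiles()
coincidence_analysis(p$ttsuv1, p$sus_scrofa)
#> <cub_coincidence> 6 coincidence / 12 antagonism
#> Virus preferred-codon endings: A=10 C=5 G=1 T=2
sid(p$ttsuv1, p$sus_scrofa)
#> <cub_sid> R = 0.8130, D = 0.0935
```

Six of the 18 synonymous families share the same preferred codon between
TTSuV1 and *Sus scrofa* (the other 12 are antagonistic); the virus prefers
A-ended codons in 10 families. The SiD distance 0.0935 says the virus codon
usage sits well apart from the host's (0 = identical, 0.5 = orthogonal).

```r
## a synthetic mutation-pressure-only panel and its ENC-plot rows
g <- generate_cds(generator_spec(n_sequences = 4, n_codons = 630,
                                 gc3_target = 0.35, seed = 42))
enc_batch(g$sequences)
#>               id   enc   gc3s   gc12 enc_expected below_curve
#> 1 simd653fe_0001 57.88 0.3746 0.4317        56.94       FALSE
#> 2 simd653fe_0002 53.29 0.3413 0.4389        55.03        TRUE
#> 3 simd653fe_0003 58.53 0.3746 0.4698        56.94       FALSE
#> 4 simd653fe_0004 56.11 0.3683 0.4786        56.60        TRUE

h <- load_host_reference("sus_scrofa")
counts <- count_codons(g$sequences[[1]])
c(cai = cai(counts, h), rcdi = rcdi(counts, h))
#>    cai   rcdi
#> 0.5819 1.5427
```

Codon choice driven only by a GC3 target scatters the points on or near the
expected ENC curve (no selection), and a gene with no host-directed codon
preference shows a mid-range CAI and an RCDI well above 1.

## Command line

```sh
inst/cli/cubkit validate genes.fasta
inst/cli/cubkit enc genes.fasta
inst/cli/cubkit adapt genes.fasta --host sus_scrofa
inst/cli/cubkit report genes.fasta --out results/ --group-by groups.tsv
inst/cli/cubkit simulate --spec sim.yaml --out sim.fasta --truth truth.tsv
```

`report` runs the whole battery and writes one TSV per module plus a
deterministic `summary.json` and `run.log`.

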