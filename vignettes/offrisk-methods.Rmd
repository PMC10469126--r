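---
title: "Transcriptome-based off-target risk scoring: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-based off-target risk scoring: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offrisk)
```

## The problem and the model

After CRISPR-Cas9 editing, expression changes observed in the mutant are
usually attributed to the on-target lesion. Off-target edits inside
transcribed regions, however, can depress the expression of unrelated genes
(through disrupted transcripts or nonsense-mediated decay) and so contaminate
the phenotype. `offrisk` quantifies that risk using only RNA-seq-derived
inputs: an assembled transcriptome (so no reference genome is needed), a
per-sample expression table for wild-type and edited groups, and gene/GO
annotation tables produced upstream.

The procedure has five stages.

1. **Site scan.** Every protospacer+PAM-shaped window on either strand of
   every contig is tested: the PAM must match its IUPAC pattern exactly
   (zero tolerance), and the protospacer may carry at most `max_mm`
   mismatches, counted position by position. A perfect (0-mismatch) match is
   an on-target site. Coordinates are 0-based, half-open, reported on the
   contig's forward strand; site sequences are written 5'→3' on the binding
   strand with mismatched protospacer bases lowercased, and tables follow the
   Cas-OFFinder column layout so existing tooling can consume them.
2. **Downregulation screen.** Per transcript, the dTPM rule flags
   `mean(TPM edited) / mean(TPM WT) < t` (strict; default `t = 0.4`). The
   dDE rule consumes an external differential-expression table and flags
   `M < 0 & p < alpha` (strict; default `alpha = 0.001`). The DE statistics
   themselves (normalisation, count model) are deliberately out of scope:
   the classification rule is the contribution here, the test is not.
3. **Deleterious join.** Candidate sites on flagged transcripts are
   deleterious off-target sites. The on-target gene — every transcript
   mapping to a gene that carries a 0-mismatch site — is excluded first,
   isoforms included. A 0-mismatch site on some *other* gene (duplicated
   sequence) is treated as an off-target, not an on-target.
4. **GO aggregation and the D-index.** For each GO term and mismatch number
   `m`, `N(m)` counts *distinct genes* (not sites) with at least one
   deleterious site at exactly `m` mismatches. The term's risk score is
   `D = sum_m N(m) * exp(4 - m)`: off-target activity falls roughly
   exponentially with mismatch count and reported off-targets concentrate at
   four or fewer mismatches, so the exponent pivots at 4, letting low-`m`
   genes dominate while `m >= 5` contributes little.
5. **Permutation calibration.** GO terms differ enormously in how many genes
   carry them (broad "parent" terms are annotated everywhere), so a single
   global threshold on D would be meaningless. Instead each term gets its own
   null: the downregulation flags are permuted across transcripts and the
   mismatch labels across site rows (both marginal distributions preserved),
   the whole downstream computation is repeated, and 100 such pseudo-D values
   define a per-term mean and spread. A D-index is significant when it
   exceeds `mean + z(1 - L/2) * sd` *and* the mean. Ten additional shuffled
   datasets, with seeds disjoint from the null seeds, estimate the
   false-positive rate: the fraction of fresh pseudo-D values that meet the
   significance rule.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_mm` | 8 (NGG) / 11 (NRR) | protospacer mismatch search bound; the two presets trade sensitivity for specificity |
| `t` | 0.4 | dTPM ratio threshold (dimensionless fold change) |
| `alpha` | 0.001 | dDE p-value threshold |
| `L` | 1e-15 or 5e-1 | confidence-level parameter of the per-term null bound |
| `n_null` | 100 | permutations forming the null |
| `n_extra` | 10 | fresh shuffles for the false-detection estimate |

The bundled presets (`approximate_dtpm`, `optimized_dtpm`, `optimized_dde`)
reproduce the three published operating points; `optimized_dtpm` is the
recommended screen for poorly annotated organisms (it yields many more
D-indices), `optimized_dde` the stricter choice where annotation is rich.

## Numerical and procedural choices

* **Parametric confidence bound.** With 100 permutations an empirical
  quantile at `L = 1e-15` does not exist, so the bound is normal-theory:
  `mean + qnorm(1 - L/2) * sd`. The quantile is computed as
  `qnorm(L/2, lower.tail = FALSE)` because `1 - L/2` rounds to 1 in double
  precision for very small `L`. The two-sided z combined with the
  "above the mean" clause makes the test effectively one-sided upper; at
  `L = 0.05` the bound is `mean + 1.96 sd`, which empirically calls ~4% of
  terms on association-free data (the skew of small-count pseudo-D
  distributions costs a little above the nominal 2.5%).
* **Population standard deviation** (divisor `n`, not `n − 1`). Immaterial at
  `n_null = 100`, but pinned for bit-reproducibility.
* **Strict inequalities everywhere** — a ratio exactly at `t`, a p-value at
  `alpha`, or a D-index exactly at its threshold or mean is *not* flagged.
* **Zero WT mean.** The TPM ratio is undefined (no pseudocount) and the
  transcript can never be dTPM: absence of WT expression is no evidence of
  downregulation. This is the only shipped behaviour.
* **Degenerate nulls.** When a term's null sd is 0 (e.g. no flag ever lands
  on its genes), significance reduces to `d_index > mean`.
* **What gets shuffled.** The construction requires breaking both the
  site–expression and the mismatch–gene associations while preserving the
  label multisets; permuting the flag column across transcripts and the
  `mm_count` column across site rows is the minimal choice that does both.
  Which columns the original procedure permuted is not documented more
  precisely than "expression profile and off-target profile"; this choice is
  stated here and fixed.
* **Two "expected true" conventions.** The expected number of true
  significant calls can be read as (total D-indices − expected false) or as
  (significant D-indices − expected false, clamped at 0). Both readings are
  defensible; `estimate_false_detection()` reports both, explicitly labelled,
  and prefers neither.
* **Both-strand scanning is the default** (transcribed regions sit on
  genomic DNA, where Cas9 can bind either strand); it is configurable.
* **Per-`m` gene counting.** A gene with deleterious sites at several
  mismatch numbers contributes once per `m`; a gene with several sites at one
  `m` contributes once. This follows from defining `N(m)` per mismatch
  number; whether the original tables deduplicated isoform-level duplicates
  before counting is unstated, so both raw-site and per-gene summaries are
  emitted by the pipeline.
* **No GO-graph propagation.** Annotations are counted exactly as supplied;
  parent terms participate only if present in the annotation table. Loose
  hierarchy effects are absorbed by the per-term permutation null instead.
* **Determinism.** Null seeds are `base_seed + 1 … + n_null`, extra seeds
  continue from there (disjoint by construction); the RNG kind is pinned, so
  the entire validation is a pure function of inputs and `base_seed`.
  D-index summation is plain double precision in ascending `m` — term counts
  are far too small for compensated summation to matter.
* The mismatch/PAM scanner is written in C++ with an early mismatch-count
  exit; tests hold it to set-equality with an exhaustive sliding-window
  oracle over random transcriptomes, both strands, at several `max_mm`/PAM
  combinations.

## What the synthetic designs emulate — and what they do not

The generators produce the full input bundle (FASTA, TPM matrix, manifest,
gene map, GO table) with exact planted ground truth. Planted windows carry
*exactly* the requested number of protospacer substitutions and a concrete
PAM; each contig is rejection-checked with the scanner so no accidental
site at or below the stated bound survives, making truth exact rather than
probabilistic. Replicate noise is multiplicative log-normal, mean-preserving,
parameterised by a coefficient of variation — the simplest model respecting
TPM positivity; it exercises the ratio rule without claiming to model
count-level dispersion.

Three frozen designs reflect the intended study conditions: three replicates
per group (the recommended minimum), NGG/8-mismatch scanning, fold changes
0.15–0.3 against `t = 0.4`, CV 0.1, and background site mismatch numbers in
the moderate-to-high range (4–8), since real potential-site catalogues are
dominated by high-mismatch loci. `strong` concentrates eight
doubly-planted (1- and 2-mismatch), strongly downregulated genes on one GO
term over a 120-transcript background; `null` (200 transcripts, 400 sites,
40 terms) has no planted association anywhere and drives the type-I checks;
`mixed` sits between and serves determinism and pipeline tests. Every design
also plants one on-target site on a downregulated transcript so the
exclusion path is always exercised.

These fixtures do **not** emulate assembly artefacts (chimeric or fragmented
contigs), mapping ambiguity between isoforms, count overdispersion, library
composition effects, or realistic GO term-size distributions. Passing tests
therefore demonstrate the correctness and calibration of the *computation*,
not the field accuracy of the screen on real data — in particular the dTPM
rule inherits all the noise of shallow replicates, which is why the
published operating points keep `t` moderate and `L` extreme.

Problem sizes used by the test suite (50-contig × 2 kb oracle comparisons,
100-seed recovery runs, 200-replicate type-I simulations, 100-permutation
nulls) were chosen so the full statistical behaviour is measurable on a
single CPU in minutes; they are the package's own test design, and the
generator parameters were fixed before the statistical tests were run.

## Known limitations

* The scanner models substitution mismatches only — no DNA/RNA bulges, and
  no activity scoring (CFD/MIT-style); `exp(4 − m)` is a frequency proxy,
  not a cleavage-efficiency model.
* Detection is confined to transcribed regions by construction; promoter or
  intergenic off-targets are invisible (an off-target in a promoter
  suppressing its gene would appear only indirectly).
* The method cannot separate downregulation *caused by* an off-target edit
  from downregulation regulated downstream of the on-target gene; the
  per-term permutation null calibrates chance co-occurrence, not causality.
* dDE quality is bounded by the upstream DE analysis consumed; no
  multiple-testing correction is added beyond the `alpha` cut.
* A transcript absent in WT (ratio undefined) can never be called, even if
  truly silenced in edited samples for other reasons.
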