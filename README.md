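# offrisk

CRISPR-Cas9 editing is judged by the phenotype of the on-target mutant, but
off-target edits can contribute to that phenotype silently. `offrisk`
assesses this risk **directly from RNA-seq data, with no reference genome**:
candidate guide-binding sites are searched on assembled transcript sequences,
intersected with transcripts that lose expression in edited samples, and the
surviving "deleterious" off-targets are aggregated to gene-ontology (GO)
terms and scored for phenotypic risk. The package is aimed at genome-editing
studies in non-model organisms, patient-derived or cancer genomes, and any
setting where the reference genome cannot be trusted to describe the edited
material.

## The method

For a guide with protospacer *P* (19–20 nt) and an IUPAC PAM pattern
(e.g. NGG), every window on either strand of every transcript whose PAM
matches exactly and whose protospacer carries at most *m*max mismatches is a
candidate site (the PAM is a hard filter; mismatches are counted on the
protospacer only).

A transcript is **downregulated** either by TPM ratio (dTPM),

    TPM ratio = mean TPM(edited) / mean TPM(WT)  <  t        (default t = 0.4)

or by an external differential-expression table (dDE): M-value < 0 and
p < α (default α = 0.001). A candidate site on a downregulated transcript is
a **deleterious off-target site**; the intended on-target gene is excluded.

Deleterious off-target genes are expanded to their GO annotations and counted
per mismatch number into the DANGER table: N(m) = number of distinct genes
with an m-mismatch deleterious site carrying the term. Each term's risk is
the **D-index**

    D = Σ_{m=0}^{m_max}  N(m) · exp(4 − m),

which weights low-mismatch (high-frequency) off-targets exponentially more,
pivoting at four mismatches. Because GO terms differ wildly in gene coverage,
each D-index is calibrated against its own permutation null: downregulation
flags are shuffled across transcripts and mismatch labels across sites 100
times, giving per-term pseudo-D-indices; a D-index above the parametric
(1 − L) confidence bound (mean + z·sd) and above the null mean is
**significant**. Ten further shuffled datasets estimate the false-positive
rate and the expected number of true significant terms.

Three presets bundle the published parameter choices: `approximate_dtpm`
(NRR PAM, ≤ 11 MM, t = 0.4, L = 5e-1), `optimized_dtpm` (NGG, ≤ 8 MM,
t = 0.4, L = 1e-15) and `optimized_dde` (NGG, ≤ 8 MM, α = 0.001, L = 1e-15).

## Worked example

```r
library(offrisk)

# a guide published for the human GRIN2B locus; two candidate off-target
# protospacers reported for it (in ALK and GBA2) are both 6-mismatch sites:
g <- example_guide()
count_mismatches(c("GCAGACTGGTTGGAAGCACC", "CCCTTCCGGCCGGAAGCGCC"),
                 g$protospacer)
#> [1] 6 6

# a synthetic dataset with a planted risk signal: eight downregulated genes
# carry 1-2-mismatch sites and share one GO term
ds    <- simulate_dataset("strong", seed = 1)
sites <- scan_transcriptome(ds$transcriptome, ds$guide, scan_preset("optimized"))
scr   <- screen_expression(ds$tpm, ds$manifest, t = 0.4)
cand  <- exclude_on_target(attach_genes(sites, ds$gene_map),
                           gene_map = ds$gene_map)
v <- validate_d_index(cand, scr, ds$annotation, criterion = "dTPM",
                      m_max = 8, config = validation_config(base_seed = 1))
glance(v)[c("total_d_index", "n_terms", "n_significant", "false_positive_rate")]
#> # A tibble: 1 × 4
#>   total_d_index n_terms n_significant false_positive_rate
#>           <dbl>   <int>         <int>               <dbl>
#> 1          680.      28             1                   0
head(tidy(v), 1)[c("go_id", "d_index", "threshold", "significant")]
#> # A tibble: 1 × 4
#>   go_id      d_index threshold significant
#>   <chr>        <dbl>     <dbl> <lgl>
#> 1 GO:0999999    222.      103. TRUE
```

The planted term (`GO:0999999`) tops the D-index ranking (222 ≈ eight genes
contributing e³ + e² each), is the only significant call at L = 1e-15, and
none of the 280 freshly shuffled pseudo-D-indices cross their thresholds
(false-positive rate 0). The total D-index over all 28 terms is 680.

File-based workflows go through `run_danger(danger_config(...))`, which
writes every stage table (Cas-OFFinder-style site list, screen CSV,
deleterious sites, DANGER table, D-index profile, significance calls, FDR
report, run manifest) to an output directory; `inst/cli/offrisk.R` exposes
the same stages as shell subcommands (`scan`, `screen`, `deleterious`,
`danger-table`, `d-index`, `validate`, `fdr`, `simulate`, `run`).

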