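# ipqms

Bait-normalized differential interactome analysis for affinity-purification
quantitative mass spectrometry (IP-QMS), built around SWI/SNF (BAF) chromatin
remodeling complexes.

## The problem

Pulling down a chromatin remodeling complex by one of its subunits (e.g. the
ATPase BRG1) or by an oncoprotein bound to it (e.g. the FUS::DDIT3 fusion of
myxoid liposarcoma) and quantifying the co-purified proteins with TMT reporter
ions yields, per IP, a protein × replicate abundance table. Comparing such
IPs across cell contexts, or a fusion-protein IP against a whole-complex IP,
answers two questions: *what does the complex look like* (subtype composition,
paralog usage) and *who rides along* (interaction partners, transcription
factors, histones). Getting there requires a chain of small, well-defined
steps, each easy to get subtly wrong:

1. **Unique-peptide aggregation** — protein abundance is the sum of its
   unique peptides; shared peptides are discarded.
2. **Quantification filter** — proteins quantified in too few samples, or
   detected only in the IgG control, are removed.
3. **Imputation** — missing reporter values are replaced by the lowest
   detected value (missingness is censoring below the detection floor).
4. **QC gate** — a bait IP whose replicates fail to enrich complex core
   components ≥ 1.5-fold over IgG (in more than one replicate) is excluded.
5. **IgG background filter** — per IP, proteins < 1.5-fold over the matched
   IgG control are background; comparisons use the intersection of the two
   retained sets.
6. **Bait normalization** — every abundance is divided by the bait's
   abundance in the same replicate, converting pull-down yield into
   per-complex composition.
7. **Differential enrichment** — per protein, fold change is the ratio of
   normalized group means; p-values from a two-sided Welch *t*-test; BH
   false-discovery rates across the comparison; significant when
   FC > 1.2 on either side and p < 0.05.

Formally, for protein *p* with normalized replicate values
x̄ₚᴬ, x̄ₚᴮ in IPs A and B:

```
FC_p = x̄_p^A / x̄_p^B,    t_p = (x̄_p^A − x̄_p^B) / √(s²_A/n_A + s²_B/n_B)
```

with Welch–Satterthwaite degrees of freedom, and BH adjustment across all
proteins in the comparison.

Downstream summaries: subtype composition means over cBAF/PBAF/GBAF-specific
subunits, per-complex fusion stoichiometry, overlap of IP-enriched proteins
with regulated genes, a 2-of-3 evidence classifier for transcription factors
(chromatin motifs / IP enrichment / RNA regulation), and single-cell
SWI/SNF co-expression analysis with a Fisher-exact independence test.

A versioned 29-gene SWI/SNF catalog ships with the package
(`inst/extdata/swisnf_catalog.tsv`), with BAF-style primary symbols and
HGNC aliases (SMARCA4 ↔ BRG1, BICRA ↔ GLTSCR1, …). Synthetic-data
generators (`simulate_ip_experiment()`, `simulate_sc_counts()`,
`simulate_tf_evidence()`) produce inputs with known ground truth so every
stage is testable without downloads.

## Worked example

```r
library(ipqms)

cfg <- ip_sim_config(
  n_proteins = 2000,
  planted_enrichment = list(
    list(class = "gbaf_specific", ip = "DDIT3:MLS", factor = 2.0),
    list(class = "pbaf_specific", ip = "DDIT3:MLS", factor = 1.6)),
  seed = 2026)
sim <- simulate_ip_experiment(cfg)

res <- run_pipeline(run_config(
  abundance = sim$matrix, design = sim$design,
  comparisons = list(
    list(a = c("BRG1", "MLS"),  b = c("BRG1", "EWS"), label = "MLS_vs_EWS"),
    list(a = c("DDIT3", "MLS"), b = c("BRG1", "MLS"), label = "DDIT3_vs_BRG1")),
  seed = 2026))

print(res$qc[["DDIT3:MLS"]])
#> QC gate for DDIT3:MLS: PASS (0/3 replicates below 1.50)
#> DDIT3_MLS_r1 DDIT3_MLS_r2 DDIT3_MLS_r3
#>       18.788       21.774       19.975

print(res$significant_counts)
#> $MLS_vs_EWS
#>   a   b
#>   0 123
#> $DDIT3_vs_BRG1
#>  a  b
#> 44  4

tab <- res$comparisons$DDIT3_vs_BRG1
subtype_enrichment_mean(tab, "gbaf_specific")   # 2.73  (planted: 2.0)
subtype_enrichment_mean(tab)                     # 2.09  (PBAF+GBAF)
bait_stoichiometry_ratio(tab, "DDIT3")           # 4.95  (implied: 5.0)
interactome_mean_enrichment(
  tab, exclude = c(core_members(load_catalog()), "BRG1"))  # 1.14
```

Reading the numbers: the QC scores (~20) are the per-replicate mean core
enrichment over IgG — the simulated pulldowns are efficient. In the
fusion-vs-whole-complex comparison the planted GBAF ×2.0 composition shift is
recovered (2.73 on three GBAF genes in one experiment; the mean over 20 seeds
converges to 2.0, see `test-acceptance.R`), and the fusion protein shows
~5× more copies per complex in its own IP, the value implied by the
generator's capture model. The 123 "significant" proteins in the MLS-vs-EWS
comparison — where nothing was planted — are a deliberate lesson: with n = 3,
the bait's own replicate noise enters every protein's normalized value as a
shared factor (here the EWS bait means drew ~23% low), coherently pushing
fold changes past the 1.2 cutoff. Single-experiment significance counts under
bait normalization deserve this grain of salt.

## Command line

```sh
Rscript inst/cli/ipqms run --config run.json --out outdir
```

writes per-comparison enrichment TSVs, significance counts, and a
reproducibility manifest (config hash, stage-by-stage retained/dropped
counts, QC outcomes). Exit codes: 0 success, 2 validation error, 3 all
comparisons skipped by the QC gate.
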