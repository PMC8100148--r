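# xciscope

Allele-specific expression analysis of X-chromosome dosage compensation in
preimplantation-embryo single-cell RNA-seq.

## The problem

In female mammals, dosage compensation between the two X chromosomes and the
single male X can in principle be achieved two ways: **X-chromosome
inactivation (XCI)** — transcriptional silencing of one X, visible as a
rising fraction of monoallelically expressed X-linked genes — or
**X dampening** — both X's lowering their output, visible as falling
expression of genes that remain biallelic. Orthogonally, **upregulation of
the active X** (Ohno's hypothesis) balances X output against the diploid
autosomes, quantified by the per-cell **X:A ratio** (median X-linked over
median autosomal expression): ≈ 1 after upregulation with one active X, and
between 1 and 2 in female cells with an upregulated X undergoing incomplete
XCI.

Discriminating these regimes from single-cell RNA-seq of preimplantation
embryos requires a chain of inferences, each implemented here as a tested,
reusable stage:

1. **Cell QC** — keep cells with ≥ 200 detected genes (among genes expressed
   in ≥ 3 cells) and strictly between 2×10⁶ and 5.1×10⁶ reads mapped to
   genes.
2. **Embryo sexing** — count Y-linked genes expressed (TPM ≥ 1) per embryo
   after removing Y genes detected in zygote/4-cell cells (where the
   transcriptome is maternal, so apparent Y signal is cross-mapping), and
   compare same-stage embryos with an unpaired Wilcoxon test. Pre-EGA
   embryos stay unsexed.
3. **Allele-specific calling** — build each embryo's genotype by pooling its
   cells' allelic counts (heterozygous iff pooled coverage ≥ 20 and pooled
   minor-allele fraction ≥ 0.20); classify each cell's SNPs at those
   positions (≥ 20 reads; alt fraction ≤ 20% or ≥ 80% → monoallelic,
   20–80% → biallelic); aggregate SNPs to genes, discarding genes whose
   SNPs disagree within a cell.
4. **X exclusion filter** — drop user-flagged escapee/pseudoautosomal
   homologues plus any X gene biallelic in a post-8-cell male cell.
5. **Dosage statistics** — per-cell monoallelic percentage (X and a control
   autosome) with Pearson stage trends; the dampening test (per-cell median
   FPKM of biallelically expressed X genes > 0.1 FPKM, compared across
   consecutive stages by Wilcoxon — a significant decrease means
   dampening); monoallelic and all-X medians; per-cell X:A ratios, both
   global (all expressed genes) and by the 100+100-gene bootstrap with
   2000 replications.

Because real accessions need raw-read processing that is out of scope, the
package ships a **synthetic cohort generator** (`sim_scenario()`,
`simulate_dataset()`) whose generative model mirrors the analysis
assumptions — per-allele expression `base × u × (active alleles) × d`,
stage-resolved silencing probability, maternal transcript carryover,
negative-binomial SNP depths with binomial/beta-binomial allelic draws — so
every stage is validated by parameter recovery against known truth.

## Worked example

Simulate the 14-embryo reference cohort layout (196 cells, 124 passing QC)
under progressive XCI with a fully upregulated active X, and run the whole
pipeline:

```r
library(xciscope)
sc <- make_reference_layout(
  p_mono = c(morula = 0.3, early_blastocyst = 0.5, late_blastocyst = 0.8),
  upregulation_factor = 2, seed = 1)
res <- run_pipeline(scenario = sc, boot_reps = 200)

res$n_cells_total; res$n_cells_retained
#> 196  ->  124 after QC
res$sex_calls[res$sex_calls$stage == "morula",
              c("embryo_id", "call", "n_y_genes_expressed", "p_value")]
#>           embryo_id   call n_y_genes_expressed      p_value
#> 6 CompactedMorula_1 female                   0 5.416498e-11
#> 7 CompactedMorula_2   male                   5 5.416498e-11
#> 8 CompactedMorula_3 female                   0 5.416498e-11
f <- subset(res$cell_summaries, sex == "female")
aggregate(cbind(pct_monoallelic_X, xa_ratio_global) ~ stage, f,
          function(x) round(mean(x, na.rm = TRUE), 2))
#>              stage pct_monoallelic_X xa_ratio_global
#> 1 early_blastocyst             51.33            1.59
#> 2  late_blastocyst             81.56            1.29
#> 3           morula             29.68            1.82
res$trends$mono_X_female
#> $r 0.9736702   $p_value 8.156455e-43   $n 66
res$dampening$verdict
#> "not_detected"
```

Reading the output: sexing is recovered exactly (males express all five
clean Y-panel genes, females none; the within-stage Wilcoxon p-value is the
evidence). The female monoallelic percentage tracks the planted silencing
probabilities (30/50/80%) and rises strongly with stage (Pearson r = 0.97).
The X:A ratio sits between 1 and 2 and falls as XCI progresses on an
upregulated X, and the dampening test correctly reports no dampening —
biallelic X genes are not losing expression even as monoallelic calls rise.

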