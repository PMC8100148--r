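---
title: "Quantifying X-linked dosage compensation from allele-specific scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying X-linked dosage compensation from allele-specific scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciscope)
```

## The inference problem

Female mammalian cells can balance X-linked dosage against males by
silencing one X (X-chromosome inactivation, XCI), and against the diploid
autosomes by upregulating the active X. A competing hypothesis for
preimplantation development — X dampening — posits that both X copies
lower their output instead. The three mechanisms leave distinct footprints
in single-cell RNA-seq with allelic resolution:

* **XCI**: the fraction of X-linked genes expressed from a single allele
  rises over developmental stages, while the expression level of genes that
  remain biallelic stays flat.
* **Dampening**: the monoallelic fraction stays flat, while biallelic
  X-linked expression falls.
* **Upregulation**: the per-cell X:A ratio (median X-linked over median
  autosomal expression, expressed genes only) moves toward 1 in males and
  sits between 1 and 2 in females with incomplete XCI on an upregulated X.

`xciscope` implements this discrimination as a pipeline of testable
stages over four inputs: a genes × cells expression matrix (FPKM and TPM),
per-cell per-SNP allele read counts (VCF with AD fields, or TSV), gene
annotation (BED), and cell metadata (embryo, stage, lineage, mapped reads).

## Stage-by-stage model and assumptions

**Cell QC.** A cell is kept iff it detects at least 200 genes — counting
only genes expressed in at least 3 cells — and its reads mapped to genes
lie strictly between 2×10⁶ and 5.1×10⁶. Both read bounds are exclusive by
definition ("more than"/"less than"), so a cell at exactly 2×10⁶ reads is
removed. The gene-detectability criterion is evaluated on the matrix as
given; the filter is idempotent in realistic cohorts but is not guaranteed
to be a mathematical projection when very few cells remain, since
detectability is relative to the cell set.

**Sexing.** Y-linked expression separates sexes only after embryonic
genome activation (EGA, the 8-cell stage here): before it the transcriptome
is maternal, so zygote/4-cell embryos are always `unsexed`, and any Y gene
detected (TPM ≥ 1) in those cells is removed from the sexing panel as
presumptive X/Y cross-mapping. The published procedure scores embryos by
two criteria (number of Y genes expressed and their level) without stating
the decision rule that combines them; we adopt: **male iff at least one
panel gene is expressed (TPM ≥ 1) in at least two cells of the embryo**,
robust to a single stray read, with the within-stage unpaired Wilcoxon
comparison of per-cell summed panel TPM reported as supporting evidence.
A gene counts as expressed in an embryo if TPM ≥ 1 in at least one retained
cell (the aggregation rule is otherwise unstated). Both thresholds are
arguments.

**Genotyping from counts.** Embryo genotypes are built by pooling all
cells of an embryo; a position is heterozygous iff pooled coverage ≥ 20
and pooled minor-allele fraction ≥ 0.20. The published analysis used a
variant caller whose effective thresholds are not recoverable; we mirror
the cell-level constants at the embryo level and expose both
(`ase_params()`), since the stated 20-read rule is ambiguous about which
level it binds. Cell-level calls are made only at the cell's own embryo's
heterozygous positions, which is what lets different cells of one embryo
reveal different silenced haplotypes.

**Allelic classification.** At a heterozygous SNP covered by ≥ 20 reads,
an alternative-allele fraction ≤ 20% or ≥ 80% is monoallelic and 20–80%
biallelic. The brackets overlap at exactly 20/80%; we assign the
boundaries to the monoallelic side (≤, ≥), keeping "0–20%" literally
closed. Gene calls require all informative SNPs of a gene in a cell to
agree; disagreement discards the gene **in that cell only** (calls are
defined per cell, so a conflict in one cell says nothing about another).
Two SNPs monoallelic for opposite alleles in the same cell still satisfy
the monoallelic rule — phase is unknown without haplotypes — and are kept
as monoallelic with `mono_allele = "mixed"` for audit.

**X exclusion filter.** X-linked analyses drop (a) genes on a
user-supplied escapee/pseudoautosomal exclusion list — treated as input,
not computation, because pseudoautosomal annotation is species-dependent
and often poor — and (b) any X gene called biallelic in at least one cell
of a male embryo after the 8-cell stage, where a single X cannot genuinely
yield two alleles. Biallelic male signal at or before the 8-cell stage is
expected from maternal transcripts and does not exclude.

**Dosage statistics.** The monoallelic percentage is
100 × mono / (mono + bi) over informative genes; cells with none are
missing, never zero. Stage trends use Pearson correlation against the
ordinal stage rank 1–6 (zygote … late blastocyst, equal spacing — the
regressor is not stated in the published figures; ranks are the neutral
choice and the encoding is an argument). Expression medians apply a strict
FPKM > 0.1 floor and are per-cell: a gene contributes to a cell's
biallelic median only with that cell's own call. The dampening verdict is
`detected` iff some consecutive-stage Wilcoxon comparison shows a
significant (α = 0.05) decrease of the biallelic medians. X:A ratios
exclude Y genes from the autosomal pool; the bootstrap estimator samples
100 + 100 genes without replacement per replication (the conventional
reading of R's `sample`), 2000 replications, per-cell median over
replications, fully seeded. Raw two-sided Mann–Whitney p-values are
reported without multiple-testing correction, matching the published
convention; stars bin at 0.05 / 10⁻³ / 10⁻⁴.

## The synthetic cohort generator

`simulate_dataset()` draws per-allele latent expression for every gene and
cell:

* autosome: each allele at base abundance $b_g \sim \mathrm{logN}(\mu, \sigma)$;
* Y gene: $b_g$ in males (single copy), 0 in females;
* X gene: each **active** allele contributes $u_t \, d_t \, b_g$ in
  females and $u_t\, b_g$ in males, where $u_t$ is the per-stage
  upregulation factor (1 = none, 2 = full single-X upregulation) and
  $d_t$ the dampening factor (1 = none);
* silencing: in a female cell at stage $t$, each non-escapee X gene is
  silenced on the cell's chosen haplotype with probability
  $p_{\mathrm{mono}}(t)$ (the haplotype is drawn per cell, or per embryo
  when `imprinted = TRUE`). With `coherent = TRUE`, a contiguous block of
  the X centred on an XIST-like locus is silenced instead, emulating the
  spatial clustering of monoallelic calls around that locus.

Pre-EGA biology is emulated by a maternal carryover mixture: a per-stage
fraction $m_t$ of each cell's transcriptome comes from a maternal pool
that is biallelic at heterozygous sites and silent on Y (defaults
$m = 1, 1, 0.3, 0.05, 0, 0$ across the six stages — pre-EGA cells are
fully maternal, with decay through the morula). This single device
produces the three pre-EGA signatures the analysis must tolerate: absent Y
expression in zygotes/4-cells, biallelic X signal in early male cells, and
its decay as maternal mRNA degrades.

Allelic counts at heterozygous SNPs (a gene is heterozygous in an embryo
with probability `het_snp_prob`; 2 SNPs per heterozygous gene by default,
matching the ~2.3 observed ratio of heterozygous positions to informative
genes in comparable data) are drawn binomially at negative-binomial depths
(default mean 60, size 5), with symmetric miscall noise folded into the
allele probability, $p' = p(1-\varepsilon) + (1-p)\varepsilon$
(ε = 0.005 by default — no allelic noise model is published, so a
per-read miscall on the order of sequencing error is the neutral choice),
and an optional beta-binomial overdispersion switch, off by default as the
simpler null. FPKM equals the summed per-allele latent abundance exactly
(the truth table is the matrix); TPM is the same latent renormalised per
cell to 10⁶, so the sexing stage (TPM-based) and the expression stages
(FPKM-based) can mix units exactly as the analysis does.

`make_reference_layout()` fixes the cohort design to the reference study's:
14 embryos (3 zygotes, one 4-cell, two 8-cell, 3 morulas, 3 early and 2
late blastocysts; 5 female), with the published per-embryo cell counts
before (196) and after (124) QC — cells planted to fail receive mapped
reads outside the (2×10⁶, 5.1×10⁶) window. Pre-EGA embryos cannot be
sexed from their transcriptomes, so their truth sexes in the layout are an
arbitrary assignment (all male), chosen so the count of female embryos
matches the published five.

**What the generator does not emulate** — and therefore what passing
recovery tests do not establish about real data: reference-mapping bias
toward the reference allele, transcript-level (isoform) structure,
lineage-specific expression beyond stage labels, bursty transcription
(expression noise is a smooth log-normal), genuinely shared
pseudoautosomal sequence (escapees are flags, not sequence homology), and
aneuploidy. Monoallelic-fraction recovery on simulations shows the
classification chain is faithful to its own generative assumptions, not
that those assumptions exhaust single-cell allelic noise.

## Numerical and validation choices

* Validation cohorts are sized so that estimator noise, not gene count,
  dominates: parameter-recovery runs use the 14-embryo layout with 120 X /
  300 autosomal genes at depth 150; dosage-algebra checks use 400 X / 800
  autosomal genes with a tighter base spread (sdlog 0.5), since the X:A
  ratio of medians carries the sampling error of both pool medians;
  bootstrap-consistency uses 1000-gene pools. These sizes are the
  package's own validation design.
* In the coherent full-silencing scenario used to verify the random-XCI
  signature (the probability that an embryo of $k$ cells exposes both
  haplotypes is $1 - 2\,(1/2)^k$), chromosome-wide silencing compresses an
  embryo's pooled minor-allele fraction — a 7:1 haplotype split pools to
  1/8 — so that check lowers the genotype MAF floor to 0.05; the default
  0.20 is appropriate whenever a biallelic fraction keeps pooled
  frequencies near balance.
* Ties and degenerate inputs: zero-coverage SNPs have undefined allelic
  fraction and are uninformative; empty gene pools yield missing (NA)
  statistics, never fabricated zeros; constant inputs to the stage trend
  are an error rather than r = 0.
* Wilcoxon tests use exact p-values where sample sizes and ties permit
  (R's default), normal approximation otherwise.

## Limitations

No haplotype phasing (hence `mixed` monoallelic calls), no RNA-editing or
mapping-bias correction, no FPKM↔TPM conversion (units are declared, never
inferred, because gene lengths are not generally recoverable), no
sex-chromosome aneuploidy detection, and no lineage-resolved (EPI vs PE)
contrasts — lineage labels pass through as metadata. Multi-allelic variant
records are skipped, not decomposed.
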