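# fatdep

Co-expression network analysis of fat-deposition transcriptomes: an
offline, fully testable R implementation of the candidate-gene pipeline
used in porcine backfat studies — differential expression per tissue and
breed, candidate-set algebra, weighted gene co-expression network analysis
(WGCNA-style) with module detection and module–trait association,
hub-gene ranking, and gene-set enrichment — validated end-to-end on
synthetic multi-tissue count data with planted ground truth.

## Who this is for

Researchers analyzing bulk RNA-seq counts from a factorial design
(breed × trait group × tissue) who want a self-contained, deterministic,
oracle-tested implementation of the standard fat-deposition workflow,
starting at the count matrix (alignment/quantification are out of scope)
and requiring no database or network access.

## The method

Starting from gene × sample counts and sample metadata:

1. **Preprocess** — drop genes with total count < 10; median-of-ratios
   size factors `s_j = median_g c_gj / geomean(c_g·)`; fit the dispersion
   trend `α(μ) = a0 + a1/μ`; apply the closed-form variance-stabilizing
   transformation
   `vst(q) = log2((1 + a1 + 2·a0·q + 2·sqrt(a0·q·(1 + a1 + a0·q)))/(4·a0))`;
   flag (never drop) outlier samples by average-linkage clustering.
2. **Differential expression** — per breed × tissue, an NB GLM
   (log link, offset `log s_j`, trend dispersion) with a Wald test;
   Cook's-distance count outliers get missing p; significant = raw
   p < 0.05. Candidates: union across tissues within breed, intersection
   across breeds.
3. **Network** — `A_ij = |cor(x_i, x_j)|^β`, β chosen by a soft-threshold
   scan against the signed scale-free fit index (cut 0.8); topological
   overlap `TOM_ij = (Σ_u A_iu A_uj + A_ij)/(min(k_i,k_j) + 1 − A_ij)`.
4. **Modules** — average-linkage clustering of `1 − TOM`; static cut with
   minimum module size 30; module eigengene = first principal component of
   the standardized module block; modules merged while eigengene
   dissimilarity `1 − cor` < 0.25.
5. **Trait statistics** — module–trait correlation (t-based p-values),
   gene significance `GS = |cor(x_i, T)|`, module membership
   `MM = cor(x_i, ME)`, module significance (mean GS), intramodular
   connectivity `kWithin`, top-30 hub genes, hub-network edge export.
6. **Enrichment** — hypergeometric over-representation against any GMT,
   BH FDR < 0.05 within category, top 10 terms.
7. **Strong candidates** — hub genes of trait-associated modules
   (module–trait p < 0.01 for the high/low indicator) that are also
   cross-breed DE candidates.

See `vignettes/fatdep-methods.Rmd` for assumptions, parameter rationale,
and limitations.

## Worked example

Simulate the bundled study design (2 breeds × 2 backfat groups × 3
tissues × 3 replicates = 36 samples, 1,500 genes: 6 planted modules plus
background and per-tissue DE genes), then run everything:

```r
library(fatdep)

design <- make_design(seed = 1)                 # 36 samples
sim    <- simulate_dataset(design, seed = 1)    # counts + ground truth
paths  <- write_fixture(sim, "fixture")
write_gmt(make_module_gene_sets(sim, seed = 1), "fixture/genesets.gmt")

cfg <- pipeline_config(paths[["counts"]], paths[["metadata"]], "out",
                       gmt = "fixture/genesets.gmt", seed = 1)
res <- run_pipeline(cfg)
cat(res$summary, sep = "\n")
```

which prints:

```
input: 1500 genes x 36 samples
after filter (total count >= 10): 1500 genes
flagged outlier samples: none
DE candidates: Landrace=1035, Songliao=1001; cross-breed intersection: 904
chosen soft threshold: beta = 18
modules: 6 (sizes 300, 269, 213, 157, 100, 67); grey: 394 genes
trait-associated modules (p < 0.01): ME1, ME2, ME3, ME4
strong candidates (trait-module hub & cross-breed DE): G00006, G00009, ...
```

Reading it: all six planted modules are recovered (the planted pure
backfat module — truth module 4, 150 genes — is detected as module 4 with
eigengene–trait correlation r = 0.945, p = 4.5e-18, the largest in the
module–trait table; three further modules carry moderate group components,
r = −0.58, 0.46, −0.50). The strong-candidate list contains hub genes of
those trait modules that are also DE in both breeds — the synthetic
analogue of prioritizing fat-deposition genes. Per-stage outputs
(`de_*.tsv`, `modules.tsv`, `module_trait.tsv`, `genestats.tsv`,
`hubs_M*.tsv`, `enrichment_*.tsv`, `summary.txt`, `manifest.json`) land in
`out/`; reruns with the same seed are byte-identical.

A minimal command-line interface wraps the same calls:

```sh
Rscript -e 'fatdep::fatdep_cli()' simulate --outdir fixture --seed 1
Rscript -e 'fatdep::fatdep_cli()' run-all --counts fixture/counts.tsv \
    --metadata fixture/metadata.tsv --gmt fixture/genesets.gmt \
    --outdir out --seed 1
```

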