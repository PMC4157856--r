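# dgetag

Digital gene expression (DGE) tag profiling for two-library designs, with
an exact test for differential expression and a ground-truthed synthetic
benchmark.

DGE tag-seq quantifies a transcriptome by sequencing a single 17 bp tag
per transcript, anchored immediately 3' of the 3'-most NlaIII restriction
site (`CATG`). It was the workhorse of early genome-wide expression
comparisons in non-model organisms — one library per condition, millions
of tags each — such as comparing gene expression between deformed and
normal chicken beak tissue. `dgetag` implements the complete analysis
path for such a design, aimed at anyone who wants to reanalyse legacy
tag-count data or benchmark the method's statistical behaviour:

* **Reference tag index** — scan gene sequences for `CATG`, derive every
  17 bp tag 3' of a site, classify tags as unambiguous (one gene) or
  ambiguous (several genes), and report the standard accounting table
  (genes with a CATG site, total/unambiguous/ambiguous reference tags).
* **Tag cleaning and mapping** — remove adaptor and ambiguous-base tags,
  drop singletons, and assign tags to genes under the perfect-match or
  1-mismatch rule, with full accounting (all mapped / unambiguous /
  unknown tags, detected genes).
* **TPM normalisation** — tags per million clean tags.
* **Differential expression** — the Audic–Claverie exact test. With
  `x` tags for a gene in library 1 (total `N1`) and `y` in library 2
  (total `N2`), the probability of observing `y` under equal expression is

  ```
  p(y|x) = (N2/N1)^y * (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )
  ```

  i.e. `y | x ~ NegBinom(size = x+1, prob = N1/(N1+N2))`. The two-sided
  p-value doubles the smaller conditional tail; genes are called
  differentially expressed when `p < 0.005`, Benjamini–Hochberg
  `FDR < 0.001` and `|log2(TPM1/TPM2)| >= 1` jointly.
* **Enrichment** — upper-tail hypergeometric test of GO/pathway term
  over-representation in a DEG set
  (`P = 1 - sum_{i<m} C(M,i) C(N-M,n-i) / C(N,n)`).
* **Saturation analysis** — detected genes as a function of sequencing
  depth on nested subsamples of the raw tag stream.
* **qPCR validation** — comparative-Ct (`2^-ddCt`) fold changes and
  per-gene t-tests on dCt for concordance checks.
* **Synthetic studies** — `simulate_study()` generates a reference
  transcriptome, annotations, and a pair of raw tag libraries with known
  per-gene abundances and injected log2 effects, so sensitivity and
  empirical FDR of the whole pipeline are measurable.

## Worked example

```r
library(dgetag)

cfg <- sim_config(n_genes = 400L, gene_length_range = c(100L, 800L),
                  n1 = 40000, n2 = 40000, frac_de = 0.08,
                  term_size_range = c(5L, 40L), seed = 14)
st  <- simulate_study(cfg)
print(st$index)
#> TagLibraryIndex: 400 genes, 375 with CATG site, 722 reference tags ( 722 unambiguous / 0 ambiguous )

cl1 <- clean_tags(st$libs$lib1); cl2 <- clean_tags(st$libs$lib2)
m1  <- map_tags(drop_singletons(cl1), st$index)
m2  <- map_tags(drop_singletons(cl2), st$index)
counts <- merge(m1$expression[, c("gene_id", "count")],
                m2$expression[, c("gene_id", "count")],
                by = "gene_id", all = TRUE)
names(counts) <- c("gene_id", "x", "y")
counts[is.na(counts)] <- 0

de <- call_degs(counts, attr(cl1, "clean_total"), attr(cl2, "clean_total"))
print(de)
#> DEResult: 321 genes tested, 17 DEGs (9 up [52.9%], 8 down [47.1%])
```

`call_degs()` reports, per gene, the two library counts, TPMs, the log2
ratio (library 1 over library 2, zero counts floored to 1), the exact-test
p-value, the BH FDR, and the up/down/ns call; the summary gives the DEG
total and the up/down split as percentages. Here 17 of the 30 injected DE
genes are recovered at 40k-tag depth with no false calls — shallow
libraries lose the weakly expressed ones, which is exactly what
`saturation_curve()` is for.

The same stages run from files via `pipeline_config()` + `run_pipeline()`
(FASTA reference, TSV tag tables, optional TSV annotations), writing all
stage outputs and a run report under an output directory.

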