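# gonadnet

Signed co-expression network analysis of gonadal-development RNA-seq time
courses, with a sex-timing procedure that dates **molecular** sex
differentiation from samples collected before the gonad can be sexed
morphologically.

The package reimplements, as a tested and reusable R pipeline, the analysis
design used for the 40-library gonadal transcriptome series of the dwarf
surfclam *Mulinia lateralis* (NCBI BioProject PRJNA862073): six timepoints
from 35 to 60 days post-fertilization (dpf), sexually undifferentiated
gonads at 35/40 dpf, and testis/ovary samples from 45 dpf on. Because the
sequencing libraries themselves are not needed to develop or validate the
method, the package ships a fully seeded synthetic time-course generator
with planted co-expression modules and complete ground truth; every stage
is exercised end to end against that truth.

## What it computes

1. **Read QC and normalization** — the post-trimming filter that removes
   reads containing undetermined bases (`N`) or more than 10 positions with
   Phred quality < 20 (`filter_reads()`), per-group sequencing summaries
   (`summarize_qc()`), TPM conversion (`counts_to_tpm()`), and the
   expressed-gene filter (group-mean TPM >= 1 in at least one of the 10
   timepoint-by-sex groups).
2. **Signed network construction** — gene-gene Spearman correlation `s`,
   signed soft-thresholded adjacency
   `a_ij = ((1 + s_ij)/2)^beta` with `beta = 15` (scale-free fit
   diagnostics via `pick_soft_power()`, target R^2 = 0.75), topological
   overlap

   `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
   `l_ij = sum_u a_iu a_uj`, `k_i = sum_j a_ij`,

   and module detection on the dissimilarity `1 - w` by average-linkage
   clustering with dynamic branch decomposition (minimum module size 100,
   cut height 0.99).
3. **Differential expression** — per-gene one-way ANOVA on `log2(TPM + 1)`
   across the 10 sample groups, Storey q-values (cubic-spline pi0
   estimate), DEGs at q < 0.01.
4. **Module characterization** — hypergeometric DEG overrepresentation
   (development-related modules at q < 0.1), intramodular connectivity
   `K_in` with top-15% hub ranking, module eigengenes, expression-archetype
   classification (gonad-forming / male- or female-specific / sexually
   shared / unrelated), and GMT-based term enrichment.
5. **Sex timing** — from each sex-specific module, up to 40 hub genes
   differentially expressed between the sexes at 45 dpf (Welch test,
   p < 0.05) are taken as markers; all samples are clustered on the marker
   profiles (correlation distance, average linkage, k = 3), clusters are
   labelled by majority vote of their sexed members, and the fraction of
   35/40-dpf samples inheriting a sex label dates molecular sex
   differentiation. A global sample PCA is also provided.

## Worked example

```r
library(gonadnet)
res <- run_pipeline(config = pipeline_config(seed = 1))

res$overrepresentation[, c("module", "module_size", "deg_fraction",
                           "q", "is_related")]
#>   module module_size deg_fraction        q is_related
#> 1     M1         160            1 8.42e-90       TRUE
#> 2     M2         150            1 5.13e-84       TRUE
#> 3     M3         140            1 2.65e-78       TRUE
#> 4     M4         140            1 2.65e-78       TRUE
#> 5     M5         130            0 1.00e+00      FALSE

res$archetypes[, c("module", "archetype", "sex_cohens_d")]
#>   module       archetype sex_cohens_d
#> 1     M1          shared      -0.0782
#> 2     M2   gonad_forming      -0.3006
#> 3     M3   male_specific       6.4997
#> 4     M4 female_specific      -6.8328
#> 5     M5       unrelated       0.1286

res$sex_timing$ratios
#>   timepoint n_assigned n_total ratio
#> 1        35          6       6     1
#> 2        40          6       6     1
```

With no real data supplied, `run_pipeline()` simulates the default
40-sample, 2,000-gene dataset (five planted modules, molecular sex
divergence at 35 dpf). The run above finds all five planted modules: four
are flagged DEG-overrepresented (every member differentially expressed,
q-values < 1e-77) while the design-independent module M5 is not; the two
sex-specific modules show sex effects of |Cohen's d| > 6 and contribute 42
marker genes (609 DEGs overall); and clustering on those markers assigns a
sex to all six undifferentiated samples at both 35 and 40 dpf — the
expected outcome when molecular divergence is planted at 35 dpf.

To analyse real tables instead, pass a TPM matrix and design data frame
(`read_expression_tsv()`, `read_design_tsv()`), or use the thin CLI wrapper
`inst/cli/gonadnet.R` (`simulate`, `qc`, `tpm`, `run-all` subcommands).

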