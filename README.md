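# polytail

Differential polyadenylation analysis from basecaller-tagged BAM files.

Nanopore sequencing of native RNA (and of cDNA) lets the basecaller estimate
the length of each read's poly(A) tail; dorado, run with `--estimate-poly-a`
against a transcriptome reference, writes the estimate into an integer BAM
auxiliary tag (`pt`). Tail length modulates transcript stability and
translation, so comparing tail-length distributions between conditions —
globally, per transcript, or per gene — identifies *differentially
polyadenylated genes* (DPGs). `polytail` is an R package for that analysis:
it extracts per-read tail lengths from tagged BAMs, attaches gene identifiers
from a GTF, and tests for group differences with an adaptive statistical
engine, producing tidy tables and publication plots.

## The statistical core

For every comparison (pooled groups, or one transcript/gene at a time) the
engine checks, per group *g* with tail lengths *x*:

* **normality** — Shapiro–Wilk for 3 ≤ n ≤ 5000, Lilliefors
  (Kolmogorov–Smirnov with estimated mean/sd) above;
* **variance homogeneity** — Brown–Forsythe Levene test
  (one-way F on |x − median(x_g)|);

and routes the comparison:

| assumptions | 2 groups | ≥ 3 groups |
|---|---|---|
| normal, homoscedastic, all n ≥ 3 | Student's *t* | one-way ANOVA + Tukey HSD |
| normal, heteroscedastic | Welch's *t* | Welch's ANOVA + Games–Howell |
| otherwise (non-normal, or any n < 3) | Wilcoxon rank-sum | Kruskal–Wallis + Dunn (Bonferroni) |

Per feature, the table carries the effect size (Cohen's
*d* = (x̄_T − x̄_C)/s_pooled), the log2 fold change of mean tail length
log2(x̄_T/x̄_C), and a BH-adjusted p-value (other corrections available). A
feature is a DPG when p.adj < 0.05 (strict); the sign of the log2 fold
change labels it **collapsed** (shortened tails) or **expansion**
(lengthened tails). Forced modes (`wilcoxon_only`, `kruskal_only`) reproduce
the purely non-parametric analysis.

Around the core: molecule counting, a minimum-tails filter (default: genes
with fewer than 10 tails are excluded), duplicate read-assignment
classification and within-gene dedup, feature × sample matrices, PCA on
median tail lengths, fixed-window tail-length binning with hierarchical
clustering, and density / volcano / MA / heatmap / PCA / duplicates plots.
A synthetic-data generator writes tagged BAM files with planted tail-length
shifts, so the whole pipeline is testable without external data.

## Worked example

Simulate a two-group experiment (50 genes, 10 with tails shortened by
25 nt in the HIGH group), write it as real tagged BAMs, and run the
pipeline:

```r
library(polytail)

design <- simulation_design(n_features = 50, n_affected = 10, shift = -25,
                            baseline_sd = 10, reads_per_feature = 30,
                            n_samples_per_group = 2, seed = 42)
exp <- write_synthetic_experiment(design, "demo")

samples <- read_samples_table(exp$samples_csv)
#> Samples table: 4 sample(s) in 2 group(s) [CTR: 2, HIGH: 2]
polya <- extract_polya(samples, tag = "pt", policy = "primary")
head(polya, 3)
#> # A tibble: 3 × 5
#>   read_id  transcript_id polyA_length sample_name group
#>   <chr>    <chr>                <int> <chr>       <chr>
#> 1 CTR_1_r1 t0001                   82 CTR_1       CTR
#> 2 CTR_1_r2 t0001                   84 CTR_1       CTR
#> 3 CTR_1_r3 t0001                   69 CTR_1       CTR

stats <- polya |>
  attach_gene_ids(parse_gtf_transcript_gene_map(exp$gtf)) |>
  filter_min_tails("gene_id", min_tails = 10) |>
  per_feature_two_group("gene_id", control_group = "CTR",
                        treated_group = "HIGH",
                        mode = "adaptive", adjust_method = "BH")
glance(stats)
#> # A tibble: 1 × 8
#>   comparison mode     adjust_method alpha level   n_features n_tested n_dpg
#>   <chr>      <chr>    <chr>         <dbl> <chr>        <int>    <int> <int>
#> 1 two_group  adaptive BH             0.05 gene_id         50       50    11

dplyr::arrange(tidy(stats), padj)[1:3, ]
#>   feature_id test_id    p_value     padj cohens_d log2fc dpg_call
#> 1 g0004      student_t 5.36e-29 1.34e-27    -2.73 -0.541 collapsed
#> 2 g0005      student_t 5.14e-29 1.34e-27    -2.73 -0.658 collapsed
#> 3 g0003      student_t 8.56e-29 1.43e-27    -2.71 -0.758 collapsed

table(stats$dpg_call)
#> collapsed expansion        ns
#>        10         1        39
```

All ten planted genes are recovered as `collapsed` (negative log2 fold
change: treated tails shorter); one null gene slips in at BH 0.05, as
expected at that FDR. The per-feature tests here are Student's *t* because
the simulated tails are normal with equal variances — on skewed features
the same call would route to Wilcoxon. The pooled comparison across all
reads:

```r
global_group_test(polya)
#> wilcoxon: statistic = 5.191e+06, p = 7.131e-25 (groups: CTR, HIGH; n = 3000, 3000)
```

(Pooling many genes gives a mixture distribution, so the engine correctly
declines the parametric branch.) Plots:

```r
autoplot(stats)                                     # volcano
plot_ma(stats)
plot_density(polya, test = global_group_test(polya))
plot_heatmap(bin_tail_lengths(polya, frame = 15, mode = "normalized"))
```

The same workflow is available from the shell through the `polytail`
script (`system.file("cli", "polytail", package = "polytail")`), with
subcommands `simulate`, `extract`, `annotate`, `qc-dups`, `dedup-genes`,
`count`, `filter`, `stats2`, `statsk`, `matrix`, `pca`, `heatmap-matrix`
and `plot`; each run writes a JSON manifest with resolved parameters and
output checksums.

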