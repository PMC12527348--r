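---
title: "Methods: adaptive differential polyadenylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive differential polyadenylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytail)
```

## The measurement and its contract

Basecallers for nanopore data can estimate, per read, how long the poly(A)
homopolymer at the 3′ end was, and store the estimate as an integer
auxiliary tag in the BAM output (dorado writes `pt` when run with
`--estimate-poly-a`). When the reads are aligned to a *transcriptome*
reference, the alignment's reference name is the read's transcript
assignment. `polytail`'s input contract is exactly that: BAM files with an
integer tail tag and transcriptome-space alignments, plus a samples table
(BAM → sample → group) and a GTF for transcript→gene mapping.

`extract_polya()` deliberately does *no* inference: one record per
alignment that (a) is mapped, (b) passes the alignment policy, and (c)
carries a tag value ≥ 1. Everything else is counted per skip reason
(`unmapped`, `filtered_by_policy`, `tag_missing`, `tag_nonpositive`) so
that emitted rows plus skips always equal alignments scanned. The default
policy keeps primary alignments only — one tail estimate per molecule.
Keeping secondaries (`policy = "all"`) is offered because multi-assigned
reads are sometimes unresolvable; the duplicate-handling functions then
classify them (`unique` / `duplicated` / `multiple` per sample) and, for
gene-level work, `drop_gene_level_duplicates()` removes records that share
(sample, read, gene, tail length) — the same molecule counted twice within
one gene — keeping the first by input order for determinism. Transcript-
level analyses keep duplicates: with no way to decide the true transcript,
dropping either record would be arbitrary.

## The adaptive testing engine

Tail-length distributions are frequently skewed and heteroscedastic, but
not always; a fixed test either wastes power (always-nonparametric) or
risks miscalibration (always-*t*). The engine therefore checks assumptions
per comparison and routes:

* **Normality** per group: Shapiro–Wilk for 3 ≤ n ≤ 5000; Lilliefors above
  (Shapiro–Wilk's implementation is defined only to n = 5000, and at such
  sizes the KS-based test is amply powered). Groups with n < 3 or constant
  values are *not assessable* and are treated as non-normal.
* **Variance homogeneity**: the Brown–Forsythe variant of Levene's test
  (absolute deviations from group *medians*, then a one-way F), chosen for
  robustness against the very non-normality it coexists with.
* Routing: all groups normal and homoscedastic and all n ≥ 3 → Student's
  *t* (2 groups) or one-way ANOVA + Tukey HSD (k > 2); normal but
  heteroscedastic → Welch's *t* or Welch's ANOVA + Games–Howell; anything
  else → Wilcoxon rank-sum or Kruskal–Wallis + Dunn with Bonferroni.

Both assumption gates use `alpha_assumption = 0.05` by default; the knob is
exposed because the gate level is a convention, not an estimate.

Numerical decisions worth knowing:

* The Wilcoxon test uses the exact null distribution when both groups have
  n ≤ 25 and there are no ties, else the normal approximation with tie and
  continuity correction. The exact path is verified against full
  enumeration of all C(n₁+n₂, n₁) rank splits (agreement to 1e-12).
* If *every* pooled observation is tied (e.g. two identical constant
  groups) the rank tests' normal approximation degenerates to 0/0; the
  engine reports p = 1 — no evidence of difference — rather than NA, and
  the per-feature loop likewise reroutes a zero-variance *t* statistic to
  the Wilcoxon branch.
* Games–Howell and Dunn post-hocs are computed in-package: Games–Howell as
  the pairwise Welch *t* referred to the studentized range
  (`ptukey(|t|·√2, k, df_Welch)`), Dunn as pooled-rank z tests with tie
  correction and Bonferroni over the k(k−1)/2 pairs. Student/Welch/F/
  Kruskal–Wallis/Levene agree with independent literal-formula oracles to
  1e-10 in the test suite; the Games–Howell p is checked against an
  external reference implementation at 1e-4, the accuracy of that
  reference's studentized-range interpolation.
* `adjust_pvalues()` excludes missing p-values from the number of tests m
  (untested features should not dilute the correction) and preserves their
  positions; `"fdr"` is an alias of `"BH"`.

## Per-feature analysis and DPG calls

`per_feature_two_group()` runs the engine (or forced Wilcoxon) per
transcript or gene between a designated control and treated group, then
adjusts p across tested features. Effect sizes: Cohen's
*d* = (x̄_T − x̄_C)/s_pooled and log2(x̄_T/x̄_C) of mean tail lengths
(defined, since tails are ≥ 1 nt). A feature with adjusted p strictly
below α = 0.05 is a DPG: `collapsed` if the fold change is negative
(shorter treated tails), `expansion` if positive. `per_feature_k_group()`
is the ≥ 3-group analogue: omnibus p plus the matching post-hoc per
feature; with no control/treated axis there is no direction, so
significant features are labelled `dpg`. The default `min_n` for testing a
feature is 1 — even a 2-observation group is testable on the Wilcoxon
branch — because the substantive support filter is `filter_min_tails()`:
by default, genes with fewer than 10 tails (per compared group) are
excluded before testing. The 10-tail floor is the conventional minimum for
gene-level calls; whether it should bind per group or in total is
genuinely ambiguous, so both scopes exist and per-group (the stricter
reading, and the one the tests consume) is the default.

`global_group_test()` pools all reads per group and applies the same tree.
Pooling across thousands of genes mixes per-gene distributions, so this
comparison essentially always routes non-parametrically — which is the
expected behaviour, not a failure of the gate.

## Matrices, PCA, binning, clustering

`count_molecules()` tallies records per feature × grouping value with mean
and median tail length; `build_feature_matrix()` pivots one statistic to
feature × sample. PCA treats samples as observations, centring but not
scaling features (the reference implementation's default; scaling would
equalise the influence of low- and high-variance genes, which is not
wanted for a length metric on a common scale). Features missing in any
sample are dropped, not imputed: a fabricated 0 nt tail is a strong wrong
statement. The default statistic is the median tail length, the robust
choice for skewed per-gene distributions. Component signs are fixed
(largest-magnitude loading positive) so runs are comparable.

`bin_tail_lengths()` tiles lengths into closed integer windows of `frame`
nt; length L falls in window ⌈L/frame⌉, so a length equal to a boundary
(10 with frame 10) belongs to the *lower* window 1–10. Windows stop at the
tile containing the longest observed tail — trailing empty windows would
only pad the heatmap. `normalized` mode converts rows to percentages
(rows sum to 100), which is what makes groups of different depth
comparable. Row clustering is agglomerative with Euclidean distance and
complete linkage — the common defaults of the heatmap stacks this feeds —
with rows pre-sorted by label so distance ties break deterministically;
the dendrogram exports to Newick via `ape`.

## Plots

All classification shown in figures is computed upstream:
`prepare_plot_points()` takes classes verbatim from `dpg_call`, the
density plot's dashed lines are the group means/medians it receives, and
the annotation p-value comes from `global_group_test()`. The volcano y
axis floors adjusted p at 1e-300 before −log10 to avoid infinities. The MA
x axis ("mean tail length") is read as the n-weighted pooled mean of the
two group means; the unweighted average is available via
`weighting = "simple"` since the definition is not standardised. Heatmaps
accept six two-colour ramps (`red_green`, `green_red`, `blue_green`,
`green_blue`, `blue_red`, `red_blue`); unknown names are an error, not a
fallback. `render()` writes the figure plus a sidecar TSV of plotted
coordinates, which is the tested surface.

## What the simulator emulates — and what it does not

`simulation_design()` / `simulate_polya_table()` generate per-read tables,
and `write_synthetic_bam()` materialises them as valid BAMs (primary
alignment per first occurrence of a read, secondary for re-occurrences,
dummy 50 nt sequence, tail length only in the tag — mirroring the
basecaller's contract). Defaults: baseline tail means drawn per gene from
70 ± 20 nt (median tails in plants and animals are typically reported
between 50 and 100 nt), sd 25 nt, truncated-normal lengths rounded to
integers ≥ 1; lognormal and shifted negative-binomial families are
available for skewed scenarios. Planted effects are additive mean shifts
in non-reference groups; duplicated (×2) and multi-mapped (×3) read ids
reuse the molecule's tail length on another transcript, which is what a
multi-assignment physically is.

The simulator does *not* emulate: basecalling error in the tail estimate
(tag values are draws from the true distribution, not noisy estimates of
a molecule), 3′ coverage bias, gene-expression correlation structure, or
realistic transcript sequences. Passing tests therefore demonstrate that
the statistical machinery is correct and calibrated under its stated
model, not that tail estimates from any particular basecaller are
unbiased.

Test problem sizes were chosen to make the relevant asymptotics visible
while keeping the default suite quick: 200 features with 30–50 reads per
group for calibration and recovery checks (null raw-p rate ≈ 5%, BH
discoveries 0 in ≥ 95/100 seeds; +20 nt shifts at sd 10 recovered with
sensitivity ≥ 0.9 and FDR ≤ 0.1), and groups of ≤ 7 for the exhaustive
Wilcoxon enumeration.

## Known limitations

* Reads are never re-assigned between transcripts; the tool trusts the
  alignments it is given. Gene/transcript-level analysis is only as good
  as the transcriptome-space BAM it receives.
* Differential *expression* on the count matrix is out of scope; the
  matrix is provided for export to dedicated tools.
* Paired or hierarchical designs (replicates nested in conditions) are not
  modelled: reads are pooled within groups, so replicate-level variance is
  not propagated. With few biological replicates and strong batch effects
  the per-feature p-values will be anticonservative — inspect the PCA.
* GFF3 is not parsed; convert to GTF first.
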