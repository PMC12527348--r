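Package: polytail
Title: Poly(A) Tail Length Extraction and Differential Polyadenylation Analysis
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts per-read poly(A) tail-length estimates from basecaller-tagged
    BAM files (integer auxiliary tag, e.g. the 'pt' tag written by dorado with
    --estimate-poly-a), maps transcripts to genes from GTF annotation, and tests
    for differential polyadenylation globally and per transcript or gene. An
    adaptive engine checks normality (Shapiro-Wilk or Lilliefors) and variance
    homogeneity (Brown-Forsythe Levene) per comparison and selects Student's t,
    Welch's t, or the Wilcoxon rank-sum test for two groups, and one-way ANOVA
    with Tukey HSD, Welch's ANOVA with Games-Howell, or Kruskal-Wallis with
    Dunn-Bonferroni post-hoc tests for three or more groups. Includes effect
    sizes (Cohen's d, log2 fold change of mean tail length), multiple-testing
    correction, feature-by-sample matrices, PCA, windowed tail-length binning
    with hierarchical clustering, publication plots (density, volcano, MA,
    heatmap, PCA, duplicates), a synthetic-data generator that writes tagged BAM
    files with planted tail lengths, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
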