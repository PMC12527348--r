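# The six two-colour heatmap ramps users may request.
HEATMAP_PALETTES <- list(
  red_green = c("red", "green"),
  green_red = c("green", "red"),
  blue_green = c("blue", "green"),
  green_blue = c("green", "blue"),
  blue_red = c("blue", "red"),
  red_blue = c("red", "blue")
)

#' Prepare volcano or MA plot coordinates from a stats table
#'
#' Classification (collapsed / expansion / ns) is taken verbatim from the
#' `dpg_call` column so plots and calls can never disagree; untested
#' features are excluded. The volcano y-axis is `-log10(padj)` with `padj`
#' floored at 1e-300 to avoid infinities. The MA x-axis is the n-weighted
#' (pooled) mean tail length across the two groups; `weighting = "simple"`
#' uses the unweighted average of the two group means instead.
#'
#' @param stats A two-group `feature_stats` table.
#' @param kind `"volcano"` or `"ma"`.
#' @param weighting For `kind = "ma"`: `"pooled"` (default) or `"simple"`.
#' @return A tibble with columns `feature_id`, `x`, `y`, `class`.
#' @export
prepare_plot_points <- function(stats, kind = c("volcano", "ma"),
                                weighting = c("pooled", "simple")) {
  kind <- match.arg(kind)
  weighting <- match.arg(weighting)
  assert_data_frame(stats)
  assert_columns(stats, c("feature_id", "padj", "log2fc", "dpg_call"),
                 arg = "stats")
  dat <- filter(as_tibble(stats), !is.na(.data$padj),
                .data$dpg_call != "not_tested")
  if (kind == "volcano") {
    tibble(
      feature_id = dat$feature_id,
      x = dat$log2fc,
      y = -log10(pmax(dat$padj, 1e-300)),
      class = dat$dpg_call
    )
  } else {
    assert_columns(dat, c("n_control", "n_treated", "mean_control",
                          "mean_treated"), arg = "stats")
    x <- if (weighting == "pooled") {
      (dat$n_control * dat$mean_control + dat$n_treated * dat$mean_treated) /
        (dat$n_control + dat$n_treated)
    } else {
      (dat$mean_control + dat$mean_treated) / 2
    }
    tibble(feature_id = dat$feature_id, x = x, y = dat$log2fc,
           class = dat$dpg_call)
  }
}

dpg_colour_scale <- function(collapsed_color, expansion_color, ns_color) {
  ggplot2::scale_colour_manual(
    values = c(collapsed = collapsed_color, expansion = expansion_color,
               ns = ns_color),
    breaks = c("collapsed", "expansion", "ns"),
    name = NULL
  )
}

#' Volcano plot of differential polyadenylation results
#'
#' @param stats A two-group `feature_stats` table.
#' @param collapsed_color Colour for significantly shortened tails.
#' @param expansion_color Colour for significantly lengthened tails.
#' @param ns_color Colour for non-significant features.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, collapsed_color = "red",
                         expansion_color = "green", ns_color = "grey60") {
  pts <- prepare_plot_points(stats, "volcano")
  alpha <- feature_stats_meta(stats)$alpha %||% 0.05
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    dpg_colour_scale(collapsed_color, expansion_color, ns_color) +
    ggplot2::labs(x = "log2 fold change (treated / control)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_bw()
}

#' MA plot of differential polyadenylation results
#'
#' @inheritParams plot_volcano
#' @param weighting Passed to [prepare_plot_points()].
#' @return A ggplot object.
#' @export
plot_ma <- function(stats, collapsed_color = "red",
                    expansion_color = "green", ns_color = "grey60",
                    weighting = "pooled") {
  pts <- prepare_plot_points(stats, "ma", weighting = weighting)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    dpg_colour_scale(collapsed_color, expansion_color, ns_color) +
    ggplot2::labs(x = "mean poly(A) tail length (nt)",
                  y = "log2 fold change (treated / control)") +
    ggplot2::theme_bw()
}

#' Density plot of tail-length distributions per group
#'
#' Overlays normalized tail-length densities per grouping value with a
#' dashed vertical line at each group's mean or median. The statistical
#' annotation, when requested, comes from [global_group_test()] — the plot
#' layer never computes statistics itself.
#'
#' @param polya A poly(A) table.
#' @param grouping_factor Column defining the groups.
#' @param stat `"median"` (default) or `"mean"` — the dashed line statistic.
#' @param test Optional `polya_test` (e.g. from [global_group_test()]) whose
#'   test id and p-value are shown in the subtitle.
#' @return A ggplot object. The line positions are attached as attribute
#'   `"stat_lines"` (a tibble) for downstream inspection.
#' @export
plot_density <- function(polya, grouping_factor = "group",
                         stat = c("median", "mean"), test = NULL) {
  stat <- match.arg(stat)
  assert_polya_table(polya)
  assert_columns(polya, grouping_factor, arg = "polya")
  fun <- if (stat == "median") stats::median else mean
  lines <- polya |>
    group_by(grouping_value = .data[[grouping_factor]]) |>
    summarise(position = fun(.data$polyA_length), .groups = "drop") |>
    mutate(stat = .env$stat)
  subtitle <- if (!is.null(test)) {
    sprintf("%s: p = %.3g", test$test_id, test$p_value)
  } else NULL
  p <- ggplot2::ggplot(
    polya, ggplot2::aes(x = .data$polyA_length,
                        colour = .data[[grouping_factor]],
                        fill = .data[[grouping_factor]])
  ) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::geom_vline(
      data = lines,
      ggplot2::aes(xintercept = .data$position,
                   colour = .data$grouping_value),
      linetype = "dashed", show.legend = FALSE
    ) +
    ggplot2::labs(x = "poly(A) tail length (nt)", y = "density",
                  colour = grouping_factor, fill = grouping_factor,
                  subtitle = subtitle) +
    ggplot2::theme_bw()
  attr(p, "stat_lines") <- lines
  p
}

#' Heatmap of a binned tail-length matrix
#'
#' Rows (grouping values) are ordered by the hierarchical clustering of
#' [cluster_groups()]; the fill uses one of six two-colour ramps.
#'
#' @param binned A [bin_tail_lengths()] result.
#' @param palette One of `"red_green"`, `"green_red"`, `"blue_green"`,
#'   `"green_blue"`, `"blue_red"`, `"red_blue"`.
#' @param cluster Order rows by hierarchical clustering (default `TRUE`
#'   when >= 2 rows).
#' @return A ggplot object.
#' @export
plot_heatmap <- function(binned, palette = "red_green", cluster = TRUE) {
  assert_data_frame(binned)
  assert_columns(binned, "grouping_value", arg = "binned")
  if (!is.character(palette) || length(palette) != 1 ||
      !palette %in% names(HEATMAP_PALETTES)) {
    stop_validation(sprintf(
      "Unknown palette '%s'; use one of %s.",
      as.character(palette)[1],
      paste(names(HEATMAP_PALETTES), collapse = ", ")
    ))
  }
  cols <- HEATMAP_PALETTES[[palette]]
  windows <- setdiff(names(binned), "grouping_value")
  row_order <- binned$grouping_value
  if (cluster && nrow(binned) >= 2) {
    hc <- cluster_groups(binned)
    row_order <- hc$labels[hc$order]
  }
  long <- tidyr::pivot_longer(as_tibble(binned), dplyr::all_of(windows),
                              names_to = "window", values_to = "value") |>
    mutate(
      window = factor(.data$window, levels = windows),
      grouping_value = factor(.data$grouping_value, levels = row_order)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window,
                                     y = .data$grouping_value,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = cols[1], high = cols[2],
                                 name = attr(binned, "mode") %||% "value") +
    ggplot2::labs(x = "poly(A) tail length window (nt)", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' PCA scores plot
#'
#' @param pca A [run_pca()] result.
#' @return A ggplot object (PC1 vs PC2, coloured by the grouping factor).
#' @export
plot_pca <- function(pca) {
  if (!inherits(pca, "polya_pca")) stop_validation("`pca` must come from run_pca().")
  ve <- pca$var_explained
  gf <- pca$grouping_factor
  ggplot2::ggplot(pca$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data[[gf]])) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      colour = gf
    ) +
    ggplot2::theme_bw()
}

#' Bar plot of read-assignment multiplicity
#'
#' @param dups A [classify_read_assignments()] result.
#' @return A ggplot object.
#' @export
plot_duplicates <- function(dups) {
  if (!inherits(dups, "duplication_summary")) {
    stop_validation("`dups` must come from classify_read_assignments().")
  }
  dat <- mutate(dups$counts,
                class = factor(.data$class,
                               levels = c("unique", "duplicated", "multiple")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$n_reads,
                                    fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "read-to-transcript assignment", y = "reads") +
    ggplot2::theme_bw()
}

#' @export
autoplot.feature_stats <- function(object, ...) plot_volcano(object, ...)

#' @export
autoplot.polya_pca <- function(object, ...) plot_pca(object)

#' @export
autoplot.binned_matrix <- function(object, ...) plot_heatmap(object, ...)

#' @export
autoplot.duplication_summary <- function(object, ...) plot_duplicates(object)

#' Render a figure to an image file with a sidecar data table
#'
#' Dispatches on `kind`, writes the figure (format decided by the file
#' extension: png, pdf or svg) and a sidecar TSV (`<path>.data.tsv`) of the
#' plotted coordinates so every figure has a testable data surface.
#' Rendering never alters its input data.
#'
#' @param kind One of `"density"`, `"volcano"`, `"ma"`, `"heatmap"`,
#'   `"pca"`, `"duplicates"`.
#' @param data The matching result object (poly(A) table, `feature_stats`,
#'   `binned_matrix`, `polya_pca`, `duplication_summary`).
#' @param path Output image path.
#' @param style Named list of options forwarded to the plot function
#'   (colours, `stat`, `palette`, `weighting`, `test`, and `width`/`height`
#'   in inches, default 7 x 5).
#' @return `path`, invisibly. The sidecar TSV sits at `paste0(path,
#'   ".data.tsv")`.
#' @export
render <- function(kind = c("density", "volcano", "ma", "heatmap", "pca",
                            "duplicates"),
                   data, path, style = list()) {
  if (!is.character(kind) || length(kind) != 1 ||
      !kind %in% c("density", "volcano", "ma", "heatmap", "pca", "duplicates")) {
    stop_validation(sprintf("Unknown plot kind '%s'.", as.character(kind)[1]))
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "pdf", "svg")) {
    stop_validation(sprintf("Unsupported image format '.%s' (use png, pdf or svg).", ext))
  }
  take <- function(name, default) style[[name]] %||% default
  pick <- switch(
    kind,
    density = {
      p <- plot_density(data, grouping_factor = take("grouping_factor", "group"),
                        stat = take("stat", "median"),
                        test = style$test)
      side <- attr(p, "stat_lines")
      list(plot = p, side = side)
    },
    volcano = list(
      plot = plot_volcano(data, take("collapsed_color", "red"),
                          take("expansion_color", "green"),
                          take("ns_color", "grey60")),
      side = prepare_plot_points(data, "volcano")
    ),
    ma = list(
      plot = plot_ma(data, take("collapsed_color", "red"),
                     take("expansion_color", "green"),
                     take("ns_color", "grey60"),
                     weighting = take("weighting", "pooled")),
      side = prepare_plot_points(data, "ma",
                                 weighting = take("weighting", "pooled"))
    ),
    heatmap = list(
      plot = plot_heatmap(data, palette = take("palette", "red_green")),
      side = as_tibble(data)
    ),
    pca = list(plot = plot_pca(data), side = data$scores),
    duplicates = list(plot = plot_duplicates(data), side = data$counts)
  )
  ggplot2::ggsave(path, plot = pick$plot,
                  width = take("width", 7), height = take("height", 5),
                  dpi = 150)
  write_polya_tsv(pick$side, paste0(path, ".data.tsv"))
  invisible(path)
}
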