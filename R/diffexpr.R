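#' Moderated two-group differential expression
#'
#' Per-gene case-vs-control comparison on the log2 scale with empirical-Bayes
#' variance moderation (\pkg{limma}). `log2FC` is the case mean minus the
#' control mean. The `shrink` switch exposes the two limit cases of the
#' moderation, mainly for cross-checking against classical statistics:
#' `"none"` is the pooled-variance Student t, `"full"` replaces every gene's
#' variance by the fitted prior variance (normal reference distribution).
#'
#' @param bundle An [expression_bundle()]; both groups need >= 2 samples.
#' @param shrink `"eb"` (default), `"none"`, or `"full"`.
#' @return A tibble, one row per gene: `gene`, `log2FC`, `t`, `p_value`, `df`.
#' @export
fit_moderated_ttest <- function(bundle, shrink = c("eb", "none", "full")) {
  stopifnot(inherits(bundle, "expression_bundle"))
  shrink <- match.arg(shrink)
  tab <- table(bundle$metadata$group)
  if (any(tab < 2)) abort("both groups need at least 2 samples.")
  design <- model.matrix(~group, data = bundle$metadata)
  fit <- limma::lmFit(bundle$matrix, design)
  if (all(fit$sigma == 0)) abort("zero residual variance in every gene; degenerate input.")
  lfc <- fit$coefficients[, "groupcase"]
  su <- fit$stdev.unscaled[, "groupcase"]
  if (shrink == "eb") {
    eb <- limma::eBayes(fit)
    tt <- eb$t[, "groupcase"]
    p <- eb$p.value[, "groupcase"]
    df <- eb$df.total
  } else if (shrink == "none") {
    tt <- lfc / (su * fit$sigma)
    df <- fit$df.residual
    p <- 2 * pt(-abs(tt), df = df)
  } else {
    eb <- limma::eBayes(fit)
    s0 <- sqrt(eb$s2.prior)
    tt <- lfc / (su * s0)
    df <- rep(Inf, length(tt))
    p <- 2 * pnorm(-abs(tt))
  }
  tibble(
    gene = rownames(bundle$matrix),
    log2FC = unname(lfc),
    t = unname(tt),
    p_value = unname(p),
    df = unname(df)
  )
}

#' Differential-expression thresholds
#'
#' Two presets reflect the two cohorts' conventions: the `"mdd"` preset keeps
#' any gene with raw p < 0.05 and a strictly nonzero fold change (the fold
#' change filter is vacuous except at exactly 0 — kept literal deliberately);
#' the `"pd"` preset additionally requires |log2FC| >= 0.5, boundary included.
#'
#' @param p_cut Raw p-value cutoff (strict `<`).
#' @param lfc_cut Non-negative |log2FC| cutoff.
#' @param lfc_inclusive If `TRUE` the cutoff is `>=`, else strict `>`.
#' @return A list of class `deg_thresholds`.
#' @export
deg_thresholds <- function(p_cut = 0.05, lfc_cut = 0, lfc_inclusive = FALSE) {
  stopifnot(p_cut > 0, p_cut < 1, lfc_cut >= 0)
  structure(list(p_cut = p_cut, lfc_cut = lfc_cut, lfc_inclusive = lfc_inclusive),
            class = "deg_thresholds")
}

#' @rdname deg_thresholds
#' @param preset `"mdd"` or `"pd"`.
#' @export
preset_thresholds <- function(preset = c("mdd", "pd")) {
  switch(match.arg(preset),
    mdd = deg_thresholds(p_cut = 0.05, lfc_cut = 0, lfc_inclusive = FALSE),
    pd  = deg_thresholds(p_cut = 0.05, lfc_cut = 0.5, lfc_inclusive = TRUE)
  )
}

#' Classify genes as up / down / not significant
#'
#' @param table Output of [fit_moderated_ttest()].
#' @param thresholds A [deg_thresholds()] object.
#' @return The input tibble with a `direction` column in
#'   `c("up", "down", "ns")`; up and down are disjoint by construction.
#' @export
select_degs <- function(table, thresholds = deg_thresholds()) {
  stopifnot(inherits(thresholds, "deg_thresholds"), nrow(table) > 0)
  pass_lfc <- if (thresholds$lfc_inclusive) {
    abs(table$log2FC) >= thresholds$lfc_cut
  } else {
    abs(table$log2FC) > thresholds$lfc_cut
  }
  sig <- table$p_value < thresholds$p_cut & pass_lfc
  table |>
    mutate(direction = case_when(
      sig & .data$log2FC > 0 ~ "up",
      sig & .data$log2FC < 0 ~ "down",
      .default = "ns"
    ))
}

#' Volcano-plot table
#'
#' @param table Output of [fit_moderated_ttest()].
#' @param thresholds A [deg_thresholds()] used for the class column.
#' @return Tibble `gene`, `log2FC`, `neg_log10_p`, `class`.
#' @export
volcano_table <- function(table, thresholds = deg_thresholds()) {
  select_degs(table, thresholds) |>
    transmute(.data$gene, .data$log2FC,
              neg_log10_p = -log10(.data$p_value),
              class = .data$direction)
}

#' Volcano plot of a differential-expression result
#'
#' @inheritParams volcano_table
#' @return A ggplot object.
#' @export
plot_volcano <- function(table, thresholds = deg_thresholds()) {
  vt <- volcano_table(table, thresholds)
  ggplot2::ggplot(vt, ggplot2::aes(.data$log2FC, .data$neg_log10_p,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
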