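#' Empirical-Bayes batch correction
#'
#' Removes additive and multiplicative per-batch effects from a merged cohort
#' with the parametric empirical-Bayes location/scale model (ComBat, via
#' \pkg{sva}). When `protect_group = TRUE` (default) the case/control indicator
#' enters the standardization design so biological signal is not absorbed into
#' the batch estimates.
#'
#' A single-batch bundle is returned unchanged with a warning — there is
#' nothing to correct. A design in which batch and group are perfectly
#' confounded cannot separate the two effects and is rejected.
#'
#' @param bundle An [expression_bundle()] with `metadata$batch` populated.
#' @param protect_group Keep the group covariate in the adjustment design.
#' @return An [expression_bundle()] of identical shape, batch-adjusted.
#' @export
combat_adjust <- function(bundle, protect_group = TRUE) {
  stopifnot(inherits(bundle, "expression_bundle"))
  batch <- bundle$metadata$batch
  if (length(unique(batch)) < 2) {
    warn("single batch: returning input unchanged.")
    return(bundle)
  }
  if (any(table(batch) < 2)) {
    abort("every batch needs at least 2 samples for empirical-Bayes adjustment.")
  }
  if (protect_group) {
    conf <- table(batch, bundle$metadata$group)
    if (all(rowSums(conf > 0) == 1)) {
      abort("batch is perfectly confounded with group; cannot protect the group effect.")
    }
    mod <- model.matrix(~group, data = bundle$metadata)
  } else {
    mod <- NULL
  }
  adj <- sva::ComBat(dat = bundle$matrix, batch = batch, mod = mod,
                     par.prior = TRUE, prior.plots = FALSE)
  out <- bundle
  out$matrix <- adj
  out
}

#' Principal component scores of a cohort
#'
#' Gene-wise mean-centered PCA of the samples, used for before/after batch
#' correction QC.
#'
#' @param bundle An [expression_bundle()].
#' @param k Number of components (default `min(5, samples - 1)`).
#' @return A tibble with `sample_id`, `group`, `batch`, score columns
#'   `PC1..PCk`, and an attribute `"explained"` holding the explained-variance
#'   fractions (non-increasing, summing to at most 1).
#' @export
pca_scores <- function(bundle, k = NULL) {
  stopifnot(inherits(bundle, "expression_bundle"))
  n <- ncol(bundle$matrix)
  k <- k %||% min(5L, n - 1L)
  if (k <= 0) abort("`k` must be positive.")
  if (k > min(dim(bundle$matrix))) abort("`k` exceeds matrix rank bound.")
  centered <- bundle$matrix - rowMeans(bundle$matrix)
  pc <- prcomp(t(centered), center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  out <- bind_cols(bundle$metadata[, c("sample_id", "group", "batch")], scores)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "explained") <- ev[seq_len(k)]
  out
}

#' Fraction of a principal component's variance attributable to batch
#'
#' The R-squared of a one-way ANOVA of the component scores on the batch
#' factor; used to quantify how much of the leading axis of variation batch
#' explains before and after correction.
#'
#' @param scores Output of [pca_scores()].
#' @param component Column name, default `"PC1"`.
#' @return A single number in \[0, 1\].
#' @export
batch_variance_fraction <- function(scores, component = "PC1") {
  if (length(unique(scores$batch)) < 2) return(0)
  f <- lm(scores[[component]] ~ factor(scores$batch))
  summary(f)$r.squared
}

#' PCA scatter plot coloured by batch
#'
#' @param scores Output of [pca_scores()].
#' @param colour `"batch"` or `"group"`.
#' @return A ggplot object.
#' @export
plot_pca <- function(scores, colour = c("batch", "group")) {
  colour <- match.arg(colour)
  ev <- attr(scores, "explained")
  lab <- function(i) {
    if (is.null(ev) || length(ev) < i) paste0("PC", i)
    else sprintf("PC%d (%.1f%%)", i, 100 * ev[i])
  }
  ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data[[colour]],
                                       shape = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}
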