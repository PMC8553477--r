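#' Pairwise Pearson correlations between two gene panels
#'
#' Computes Pearson r for every (crosstalk, panel) gene pair over a chosen
#' sample subset. Zero-variance genes yield an undefined correlation: those
#' pairs are reported as `NA` with a warning and are excluded downstream.
#'
#' @param bundle An [expression_bundle()].
#' @param genes_a,genes_b Character vectors of gene symbols present in the
#'   bundle (pairs are formed A x B).
#' @param samples Optional character vector of sample ids; default all.
#' @return A tibble `gene_a`, `gene_b`, `r`.
#' @export
pairwise_correlation <- function(bundle, genes_a, genes_b, samples = NULL) {
  stopifnot(inherits(bundle, "expression_bundle"))
  genes_a <- toupper(genes_a); genes_b <- toupper(genes_b)
  missing <- setdiff(c(genes_a, genes_b), rownames(bundle$matrix))
  if (length(missing)) {
    abort(paste0("genes absent from bundle: ", paste(head(missing, 5), collapse = ", ")))
  }
  samples <- samples %||% colnames(bundle$matrix)
  if (length(samples) < 3) abort("need at least 3 samples for a correlation.")
  xa <- t(bundle$matrix[genes_a, samples, drop = FALSE])
  xb <- t(bundle$matrix[genes_b, samples, drop = FALSE])
  const_a <- genes_a[apply(xa, 2, sd) == 0]
  const_b <- genes_b[apply(xb, 2, sd) == 0]
  if (length(const_a) + length(const_b) > 0) {
    warn(paste0("zero-variance gene(s) in subset, correlations undefined: ",
                paste(unique(c(const_a, const_b)), collapse = ", ")))
  }
  r <- suppressWarnings(cor(xa, xb))
  tibble(
    gene_a = rep(genes_a, times = length(genes_b)),
    gene_b = rep(genes_b, each = length(genes_a)),
    r = as.vector(r)
  )
}

#' Case, control and all-sample correlations for every pair
#'
#' @inheritParams pairwise_correlation
#' @return A tibble `gene_a`, `gene_b`, `cc_case`, `cc_control`, `cc_all`.
#' @export
pair_correlations <- function(bundle, genes_a, genes_b) {
  md <- bundle$metadata
  subsets <- list(
    cc_case = md$sample_id[md$group == "case"],
    cc_control = md$sample_id[md$group == "control"],
    cc_all = md$sample_id
  )
  out <- NULL
  for (nm in names(subsets)) {
    pc <- pairwise_correlation(bundle, genes_a, genes_b, subsets[[nm]])
    pc <- rename(pc, !!nm := "r")
    out <- if (is.null(out)) pc else left_join(out, pc, by = c("gene_a", "gene_b"))
  }
  out
}

#' Screen correlation pairs at a |r| cutoff
#'
#' Keeps pairs whose screening correlation exceeds the cutoff in absolute
#' value, strictly (`|r| > cc_cut`; a pair at exactly the cutoff is excluded).
#' By convention the screen uses the case-group correlation; whether case-only
#' or all-sample correlations are screened is a switch.
#'
#' @param correlations Output of [pair_correlations()].
#' @param cc_cut Cutoff, default 0.5.
#' @param screen_on `"case"` (default) or `"all"`.
#' @return The significant subset of `correlations`; pairs with undefined
#'   screening correlation are dropped.
#' @export
screen_pairs <- function(correlations, cc_cut = 0.5, screen_on = c("case", "all")) {
  screen_on <- match.arg(screen_on)
  col <- if (screen_on == "case") "cc_case" else "cc_all"
  correlations |>
    filter(!is.na(.data[[col]]), abs(.data[[col]]) > cc_cut)
}

# closed-form simple OLS of y ~ beta*x + beta0 with the slope's standard error
ols_line <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(NULL)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  beta0 <- mean(y) - beta * mean(x)
  rss <- sum((y - beta0 - beta * x)^2)
  s2 <- if (n > 2) rss / (n - 2) else 0
  list(beta = beta, beta0 = beta0, sd = sqrt(s2 / sxx), n = n)
}

#' Per-group regressions for one crosstalk-panel gene pair
#'
#' Fits `y ~ beta * x + beta0` by ordinary least squares separately in the
#' case and the control group, where `x` is the crosstalk gene and `y` the
#' panel (neuropeptide) gene. `sd` is the standard error of the slope
#' estimate, `s_resid / sqrt(sum((x - mean(x))^2))`; it is exactly 0 on
#' noise-free collinear input.
#'
#' @param bundle An [expression_bundle()].
#' @param gene_x Crosstalk gene (predictor).
#' @param gene_y Panel gene (response).
#' @return A tibble with rows `case` and `control`: `group`, `beta`, `beta0`,
#'   `sd`, `n`.
#' @export
fit_group_regressions <- function(bundle, gene_x, gene_y) {
  stopifnot(inherits(bundle, "expression_bundle"))
  gene_x <- toupper(gene_x); gene_y <- toupper(gene_y)
  md <- bundle$metadata
  rows <- map(c("case", "control"), function(g) {
    ids <- md$sample_id[md$group == g]
    if (length(ids) < 3) abort(paste0("group '", g, "' has fewer than 3 samples."))
    x <- bundle$matrix[gene_x, ids]
    y <- bundle$matrix[gene_y, ids]
    fit <- ols_line(x, y)
    if (is.null(fit)) {
      abort(paste0("crosstalk gene ", gene_x, " is constant in the ", g,
                   " group for pair (", gene_x, ", ", gene_y, ")."))
    }
    tibble(group = g, beta = fit$beta, beta0 = fit$beta0, sd = fit$sd, n = fit$n)
  })
  bind_rows(rows)
}

#' Differentially-regulated-link statistic
#'
#' The DRL score of a crosstalk-panel gene pair contrasts the per-group
#' regression slopes, scaled by their combined standard error, and adds the
#' all-sample correlation:
#'
#' \deqn{DRL = \frac{\beta_{case} - \beta_{control}}
#'   {\sqrt{sd_{case}^2 + sd_{control}^2}} + CC^{all}}
#'
#' A positive value is read as consistent regulation of the pair in case and
#' control samples, a negative value as opposite regulation modes. (The
#' additive correlation term can in principle flip the sign of a small slope
#' contrast; the sign is interpreted literally per the formula.)
#'
#' @param beta_case,beta_control Per-group OLS slopes.
#' @param sd_case,sd_control Standard errors of the slope estimates (>= 0).
#' @param cc_all Pearson correlation over all samples of the disease.
#' @return A numeric vector of DRL values (vectorized over the inputs).
#' @export
compute_drl <- function(beta_case, beta_control, sd_case, sd_control, cc_all) {
  if (any(sd_case < 0 | sd_control < 0)) abort("slope standard errors must be >= 0.")
  denom2 <- sd_case^2 + sd_control^2
  if (any(denom2 == 0)) {
    abort("sd_case and sd_control are both zero for some pair (noise-free input); DRL undefined.")
  }
  (beta_case - beta_control) / sqrt(denom2) + cc_all
}

#' Sign class of a DRL value
#'
#' @param drl Numeric vector of DRL values.
#' @return `"consistent"` for positive, `"opposite"` for negative, `"zero"`
#'   at exactly zero.
#' @export
drl_sign_class <- function(drl) {
  case_when(drl > 0 ~ "consistent", drl < 0 ~ "opposite", .default = "zero")
}

#' DRL records for one disease
#'
#' Correlation screening followed by per-group regressions and the DRL score
#' for every surviving crosstalk-panel pair. Pairs whose regression
#' preconditions fail (constant predictor within a group) are dropped with a
#' message, never silently.
#'
#' @param bundle An [expression_bundle()].
#' @param crosstalk,panel Character vectors of gene symbols.
#' @inheritParams screen_pairs
#' @return A tibble, one row per screened pair: `disease`, `crosstalk`,
#'   `neuropeptide`, `beta_case`, `beta_control`, `beta0_case`,
#'   `beta0_control`, `sd_case`, `sd_control`, `cc_case`, `cc_all`, `drl`,
#'   `sign_class`, ordered by (crosstalk, neuropeptide).
#' @export
drl_records <- function(bundle, crosstalk, panel, cc_cut = 0.5,
                        screen_on = c("case", "all")) {
  screen_on <- match.arg(screen_on)
  if (length(crosstalk) == 0 || length(panel) == 0) {
    return(empty_drl_tbl())
  }
  cors <- pair_correlations(bundle, crosstalk, panel)
  kept <- screen_pairs(cors, cc_cut = cc_cut, screen_on = screen_on)
  if (nrow(kept) == 0) return(empty_drl_tbl())
  rows <- pmap(kept, function(gene_a, gene_b, cc_case, cc_control, cc_all) {
    reg <- tryCatch(fit_group_regressions(bundle, gene_a, gene_b),
                    error = function(e) {
                      inform(paste0("dropping pair (", gene_a, ", ", gene_b, "): ",
                                    conditionMessage(e)))
                      NULL
                    })
    if (is.null(reg)) return(NULL)
    rc <- reg[reg$group == "case", ]; rn <- reg[reg$group == "control", ]
    if (rc$sd^2 + rn$sd^2 == 0) {
      inform(paste0("dropping pair (", gene_a, ", ", gene_b,
                    "): zero slope standard error in both groups."))
      return(NULL)
    }
    d <- compute_drl(rc$beta, rn$beta, rc$sd, rn$sd, cc_all)
    tibble(disease = bundle$disease, crosstalk = gene_a, neuropeptide = gene_b,
           beta_case = rc$beta, beta_control = rn$beta,
           beta0_case = rc$beta0, beta0_control = rn$beta0,
           sd_case = rc$sd, sd_control = rn$sd,
           cc_case = cc_case, cc_all = cc_all,
           drl = d, sign_class = drl_sign_class(d))
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) return(empty_drl_tbl())
  arrange(out, .data$crosstalk, .data$neuropeptide)
}

empty_drl_tbl <- function() {
  tibble(disease = character(), crosstalk = character(), neuropeptide = character(),
         beta_case = double(), beta_control = double(),
         beta0_case = double(), beta0_control = double(),
         sd_case = double(), sd_control = double(),
         cc_case = double(), cc_all = double(),
         drl = double(), sign_class = character())
}

#' Cross-disease DRL table
#'
#' Runs [drl_records()] for both diseases and joins the records on the
#' (crosstalk, neuropeptide) pair for side-by-side comparison of regulation
#' intensity across diseases.
#'
#' @param bundle_a,bundle_b The two disease bundles.
#' @inheritParams drl_records
#' @return A list with elements `per_disease` (the two stacked record tables)
#'   and `joined` (pairs screened in both diseases, columns suffixed by
#'   disease label).
#' @export
drl_table <- function(bundle_a, bundle_b, crosstalk, panel, cc_cut = 0.5,
                      screen_on = c("case", "all")) {
  screen_on <- match.arg(screen_on)
  ra <- drl_records(bundle_a, crosstalk, panel, cc_cut, screen_on)
  rb <- drl_records(bundle_b, crosstalk, panel, cc_cut, screen_on)
  keep <- c("crosstalk", "neuropeptide", "beta_case", "beta_control", "drl", "sign_class")
  joined <- inner_join(
    select(ra, all_of(keep)), select(rb, all_of(keep)),
    by = c("crosstalk", "neuropeptide"),
    suffix = paste0("_", c(
      if (nrow(ra)) ra$disease[1] else bundle_a$disease,
      if (nrow(rb)) rb$disease[1] else bundle_b$disease
    ))
  )
  list(per_disease = bind_rows(ra, rb), joined = joined)
}

#' Export an edge table as SIF
#'
#' Simple interaction format: `source <tab> relation <tab> target`, one edge
#' per line; an optional numeric attribute is written alongside as a
#' two-column edge-attribute file understood by Cytoscape.
#'
#' @param edges Data frame with at least two columns (source, target).
#' @param path Output `.sif` path.
#' @param relation Interaction type string.
#' @param attribute Optional name of a numeric column in `edges` written to
#'   `<path>.<attribute>.attrs`.
#' @return The SIF path, invisibly.
#' @export
write_sif <- function(edges, path, relation = "pp", attribute = NULL) {
  src <- edges[[1]]; tgt <- edges[[2]]
  writeLines(paste(src, relation, tgt, sep = "\t"), path)
  if (!is.null(attribute)) {
    apath <- paste0(path, ".", attribute, ".attrs")
    hdr <- paste0(attribute)
    lines <- paste0(src, " (", relation, ") ", tgt, " = ", edges[[attribute]])
    writeLines(c(hdr, lines), apath)
  }
  invisible(path)
}
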