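#' Crosstalk genes: intersection of two DEG sets
#'
#' A crosstalk gene is differentially expressed (up or down) in both diseases.
#' Direction and fold change are retained per disease.
#'
#' @param deg_a,deg_b Outputs of [select_degs()] for the two diseases.
#' @param labels Length-2 character vector naming the diseases; used as column
#'   suffixes.
#' @return A tibble `gene`, `direction_<a>`, `log2FC_<a>`, `direction_<b>`,
#'   `log2FC_<b>`, sorted by gene.
#' @export
intersect_degs <- function(deg_a, deg_b, labels = c("A", "B")) {
  stopifnot(length(labels) == 2)
  pick <- function(tab, lab) {
    tab |>
      filter(.data$direction != "ns") |>
      select("gene", "direction", "log2FC") |>
      rename_with(~ paste0(.x, "_", lab), c("direction", "log2FC"))
  }
  inner_join(pick(deg_a, labels[1]), pick(deg_b, labels[2]), by = "gene") |>
    arrange(.data$gene)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated — name, description, then members.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `description` attribute per element dropped (descriptions are kept in a
#'   `"descriptions"` attribute on the list).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- map(parts, ~ unique(toupper(.x[-(1:2)])))
  names(sets) <- map_chr(parts, 1)
  attr(sets, "descriptions") <- setNames(map_chr(parts, 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- imap(sets, function(members, name) {
    desc <- if (!is.null(descriptions) && name %in% names(descriptions)) {
      descriptions[[name]]
    } else "na"
    paste(c(name, desc, members), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the query set overlaps it more than
#' expected by chance when drawing `n = |query|` genes from a universe of `N`
#' genes of which `K` belong to the set: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`. One-sided over-representation only. Sets are
#' intersected with the universe before testing; raw p-values are reported
#' (the screening convention is raw `p < p_cut`), with optional
#' Benjamini-Hochberg correction available but off by default.
#'
#' @param query Character vector of genes; must be a subset of `universe`.
#' @param collections Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector: the enrichment background (typically all
#'   genes present after merging; the background is a deliberate knob).
#' @param p_cut Significance cutoff on the raw p-value.
#' @param adjust Apply Benjamini-Hochberg and report `p_adjusted`.
#' @return A tibble sorted by p: `set`, `k`, `K`, `n`, `N`, `p_value`,
#'   (`p_adjusted`,) `significant`, `overlap` (list column of gene vectors).
#' @export
hypergeometric_enrichment <- function(query, collections, universe,
                                      p_cut = 0.05, adjust = FALSE) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) abort("empty universe.")
  query <- unique(toupper(query))
  if (!all(query %in% universe)) abort("query must be a subset of the universe.")
  n <- length(query)
  N <- length(universe)
  rows <- imap(collections, function(members, name) {
    set_u <- intersect(unique(toupper(members)), universe)
    K <- length(set_u)
    hits <- intersect(query, set_u)
    k <- length(hits)
    # P(X >= k); phyper(k-1, ..., lower.tail = FALSE)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = name, k = k, K = K, n = n, N = N,
           p_value = min(p, 1), overlap = list(sort(hits)))
  })
  out <- list_rbind(rows) |> arrange(.data$p_value, .data$set)
  if (adjust) {
    out <- out |> mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"))
    out$significant <- out$p_adjusted < p_cut
  } else {
    out$significant <- out$p_value < p_cut
  }
  relocate(out, "overlap", .after = last_col())
}
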