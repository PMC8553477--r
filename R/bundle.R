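#' Expression bundle: one disease cohort
#'
#' An `expression_bundle` holds a genes-by-samples log2 expression matrix
#' together with per-sample metadata for a single disease cohort. It is the
#' unit of work for batch correction, differential expression and all
#' downstream stages.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene symbols,
#'   upper-cased on ingest), samples in columns (colnames = sample ids).
#' @param metadata Data frame with one row per sample: columns `sample_id`,
#'   `group` (`"case"` or `"control"`) and `batch` (dataset id). Rows are
#'   reordered to match the matrix columns.
#' @param disease Label for the cohort (e.g. `"MDD"`, `"PD"`).
#'
#' @return An object of class `expression_bundle`: a list with elements
#'   `matrix` (genes x samples), `metadata` (tibble) and `disease`.
#' @export
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'   dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' md <- tibble::tibble(sample_id = paste0("S", 1:5),
#'   group = c("case", "case", "case", "control", "control"), batch = "b1")
#' expression_bundle(m, md, disease = "demo")
expression_bundle <- function(matrix, metadata, disease = "disease") {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    abort("`matrix` must carry gene rownames and sample colnames.")
  }
  metadata <- as_tibble(metadata)
  required <- c("sample_id", "group", "batch")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    abort(paste0("metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  rownames(matrix) <- toupper(rownames(matrix))
  if (anyDuplicated(rownames(matrix))) {
    abort("duplicate gene symbols in matrix; collapse probes first.")
  }
  if (!all(is.finite(matrix))) abort("expression matrix contains non-finite values.")
  if (!setequal(metadata$sample_id, colnames(matrix)) ||
      nrow(metadata) != ncol(matrix)) {
    abort("metadata sample_id set must match matrix colnames exactly.")
  }
  metadata <- metadata[match(colnames(matrix), metadata$sample_id), ]
  bad <- setdiff(unique(metadata$group), c("case", "control"))
  if (length(bad)) {
    abort(paste0("group labels must be 'case'/'control'; found: ",
                 paste(bad, collapse = ", ")))
  }
  metadata$group <- factor(metadata$group, levels = c("control", "case"))
  metadata$batch <- as.character(metadata$batch)
  structure(
    list(matrix = matrix, metadata = metadata, disease = disease),
    class = "expression_bundle"
  )
}

#' @export
print.expression_bundle <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf(
    "<expression_bundle> %s: %d genes x %d samples (%d case / %d control, %d batch%s)\n",
    x$disease, nrow(x$matrix), ncol(x$matrix),
    tab[["case"]], tab[["control"]],
    length(unique(x$metadata$batch)),
    if (length(unique(x$metadata$batch)) == 1) "" else "es"
  ))
  invisible(x)
}

#' @export
dim.expression_bundle <- function(x) dim(x$matrix)

#' Write / read an expression bundle as TSV
#'
#' The on-disk form is two plain-text files: `<stem>_expr.tsv` (first column
#' `gene`, remaining columns one per sample) and `<stem>_meta.tsv`
#' (`sample_id`, `group`, `batch`).
#'
#' @param bundle An [expression_bundle()].
#' @param stem Path stem; `_expr.tsv` / `_meta.tsv` are appended.
#' @return `write_bundle_tsv()` returns the two paths invisibly;
#'   `read_bundle_tsv()` returns the reconstructed bundle.
#' @export
write_bundle_tsv <- function(bundle, stem) {
  expr_path <- paste0(stem, "_expr.tsv")
  meta_path <- paste0(stem, "_meta.tsv")
  expr <- as_tibble(bundle$matrix, rownames = "gene")
  readr::write_tsv(expr, expr_path)
  readr::write_tsv(bundle$metadata, meta_path)
  invisible(c(expr = expr_path, meta = meta_path))
}

#' @rdname write_bundle_tsv
#' @param disease Disease label to attach on read.
#' @export
read_bundle_tsv <- function(stem, disease = "disease") {
  expr <- readr::read_tsv(paste0(stem, "_expr.tsv"), show_col_types = FALSE)
  meta <- readr::read_tsv(paste0(stem, "_meta.tsv"), show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene
  expression_bundle(m, meta, disease = disease)
}

#' Collapse probe-level rows to gene symbols
#'
#' Microarray platforms measure several probes per gene; expression per gene is
#' taken as the arithmetic mean of its probes, computed per sample. Probes
#' absent from the map (or mapped to `NA`/empty symbols) are dropped. Genes are
#' ordered lexicographically so the result is deterministic regardless of probe
#' order.
#'
#' @param probe_matrix Numeric matrix with probe ids as rownames.
#' @param probe_map Data frame with columns `probe_id`, `symbol` (many probes
#'   to one symbol; `probe_id` must be unique).
#' @param metadata,disease Passed to [expression_bundle()].
#' @return An [expression_bundle()] with one row per mapped gene.
#' @export
collapse_probes <- function(probe_matrix, probe_map, metadata, disease = "disease") {
  probe_map <- as_tibble(probe_map)
  if (!all(c("probe_id", "symbol") %in% names(probe_map))) {
    abort("`probe_map` needs columns probe_id and symbol.")
  }
  if (nrow(probe_map) == 0) abort("empty probe map.")
  if (anyDuplicated(probe_map$probe_id)) abort("probe_map probe_id must be unique.")
  probe_map <- probe_map |>
    filter(!is.na(.data$symbol), .data$symbol != "") |>
    mutate(symbol = toupper(.data$symbol))
  keep <- intersect(rownames(probe_matrix), probe_map$probe_id)
  if (length(keep) == 0) abort("no probe in the matrix maps to a gene symbol.")
  sym <- probe_map$symbol[match(keep, probe_map$probe_id)]
  sub <- probe_matrix[keep, , drop = FALSE]
  # rowsum() sums per symbol; divide by probe multiplicity for the mean
  summed <- rowsum(sub, group = sym)
  counts <- as.vector(table(sym)[rownames(summed)])
  collapsed <- summed / counts
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  expression_bundle(collapsed, metadata, disease = disease)
}

#' Merge several cohorts of one disease into a single bundle
#'
#' Gene set is the intersection across the input bundles; samples are
#' concatenated. Each sample's `batch` is set to the source dataset id; sample
#' ids are prefixed with the dataset id when they collide across datasets.
#'
#' @param bundles Named list of [expression_bundle()]s (names become batch
#'   ids; unnamed lists get `dataset1`, `dataset2`, ...). All must share the
#'   disease label.
#' @return One merged [expression_bundle()].
#' @export
merge_datasets <- function(bundles) {
  if (length(bundles) == 0) abort("need at least one bundle.")
  if (is.null(names(bundles)) || any(names(bundles) == "")) {
    names(bundles) <- paste0("dataset", seq_along(bundles))
  }
  diseases <- unique(map_chr(bundles, "disease"))
  if (length(diseases) != 1) {
    abort(paste0("bundles mix disease labels: ", paste(diseases, collapse = ", ")))
  }
  genes <- Reduce(intersect, map(bundles, ~ rownames(.x$matrix)))
  if (length(genes) == 0) abort("empty gene intersection across datasets.")
  genes <- sort(genes)

  all_ids <- unlist(map(bundles, ~ .x$metadata$sample_id), use.names = FALSE)
  collide <- anyDuplicated(all_ids) > 0

  pieces <- imap(bundles, function(b, id) {
    m <- b$matrix[genes, , drop = FALSE]
    md <- b$metadata
    md$batch <- id
    if (collide) {
      md$sample_id <- paste(id, md$sample_id, sep = "_")
      colnames(m) <- md$sample_id
    }
    list(m = m, md = md)
  })
  mat <- do.call(cbind, map(pieces, "m"))
  md <- bind_rows(map(pieces, "md")) |> mutate(group = as.character(.data$group))
  expression_bundle(mat, md, disease = diseases)
}
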