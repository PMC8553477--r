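#' Load study inputs written by [make_demo()]
#'
#' @param dir Directory holding `<disease>_expr.tsv` / `<disease>_meta.tsv`
#'   pairs plus `neuropeptides.txt`, `pathways.gmt` and `ppi_edges.tsv`.
#' @param diseases Disease labels (file stems are their lower case).
#' @return A list with `bundles`, `neuropeptides`, `ppi_edges`, `pathways` —
#'   the shape [run_pipeline()] consumes.
#' @export
load_study_inputs <- function(dir, diseases = c("MDD", "PD")) {
  bundles <- setNames(
    map(diseases, ~ read_bundle_tsv(file.path(dir, tolower(.x)), disease = .x)),
    diseases
  )
  list(
    bundles = bundles,
    neuropeptides = readLines(file.path(dir, "neuropeptides.txt")),
    ppi_edges = readr::read_tsv(file.path(dir, "ppi_edges.tsv"),
                                show_col_types = FALSE),
    pathways = read_gmt(file.path(dir, "pathways.gmt"))
  )
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full crosstalk analysis pipeline
#'
#' Executes, in order: batch correction per disease (with before/after PCA
#' QC), moderated-t differential expression under per-disease thresholds,
#' crosstalk intersection, gene-set enrichment, correlation screening and DRL
#' computation, PPI direct/bridge extraction with topology metrics, the
#' tripartite crosstalk-pathway-neuropeptide network, and lasso/ROC screening
#' of the panel. Each stage's table is written as TSV under `outdir`; in/out
#' counts of every filter are reported via messages. Identical inputs and
#' seed give identical outputs.
#'
#' @param inputs A `synth_study` from [simulate_study()], or a list with
#'   elements `bundles` (named list of [expression_bundle()]s, panel rows
#'   included), `neuropeptides`, `ppi_edges`, `pathways` (see
#'   [load_study_inputs()]).
#' @param outdir Output directory (created if missing).
#' @param thresholds Named list of [deg_thresholds()] per disease; defaults to
#'   [preset_thresholds()] chosen by disease name (`"MDD"` -> mdd preset,
#'   anything else -> pd preset).
#' @param cc_cut,screen_on Correlation screening settings (see
#'   [screen_pairs()]).
#' @param lasso_lambda,folds,cv_loss,lasso_family Lasso settings (see
#'   [lasso_screen()]).
#' @param batch_correct Apply [combat_adjust()] (skipped automatically for
#'   single-batch cohorts, which it leaves unchanged anyway).
#' @param seed Integer seed for the stochastic stages (CV folds).
#' @return A `pipeline_result`: list with every stage's table, plus
#'   `manifest` (tibble `stage`, `file`, `rows`) and `params`.
#' @export
run_pipeline <- function(inputs, outdir,
                         thresholds = NULL,
                         cc_cut = 0.5, screen_on = c("case", "all"),
                         lasso_lambda = c("min", "1se"), folds = 10,
                         cv_loss = c("deviance", "mse"),
                         lasso_family = c("binomial", "gaussian"),
                         batch_correct = TRUE, seed = 1) {
  screen_on <- match.arg(screen_on)
  lasso_lambda <- match.arg(lasso_lambda)
  cv_loss <- match.arg(cv_loss)
  lasso_family <- match.arg(lasso_family)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  bundles <- inputs$bundles
  nps <- toupper(inputs$neuropeptides)
  diseases <- names(bundles)
  if (is.null(thresholds)) {
    thresholds <- setNames(map(diseases, function(d) {
      preset_thresholds(if (toupper(d) == "MDD") "mdd" else "pd")
    }), diseases)
  }

  manifest <- list()
  emit <- function(tab, stage, file) {
    path <- file.path(outdir, file)
    readr::write_tsv(tab, path)
    manifest[[stage]] <<- tibble(stage = stage, file = file, rows = nrow(tab))
    tab
  }

  # 1. batch correction + PCA QC
  pca_tabs <- list(); corrected <- list()
  for (d in diseases) {
    corrected[[d]] <- stage_run("batch_correction", {
      if (batch_correct) combat_adjust(bundles[[d]]) else bundles[[d]]
    })
    before <- pca_scores(bundles[[d]], k = 2)
    after <- pca_scores(corrected[[d]], k = 2)
    pca_tabs[[d]] <- bind_rows(
      mutate(before, stage = "before", disease = d),
      mutate(after, stage = "after", disease = d)
    )
    inform(sprintf("[%s] batch PC1 variance fraction: %.3f -> %.3f", d,
                   batch_variance_fraction(before),
                   batch_variance_fraction(after)))
  }
  emit(bind_rows(pca_tabs), "pca_qc", "pca_scores.tsv")

  # 2. differential expression per disease
  degs <- list()
  for (d in diseases) {
    tab <- stage_run("diffexpr", {
      select_degs(fit_moderated_ttest(corrected[[d]]), thresholds[[d]])
    })
    inform(sprintf("[%s] DEGs: %d up, %d down of %d genes", d,
                   sum(tab$direction == "up"), sum(tab$direction == "down"),
                   nrow(tab)))
    degs[[d]] <- emit(tab, paste0("deg_", d), paste0("deg_", tolower(d), ".tsv"))
  }

  # 3. crosstalk intersection (panel genes are not crosstalk candidates)
  crosstalk_tab <- stage_run("crosstalk", {
    ct <- intersect_degs(degs[[1]], degs[[2]], labels = diseases)
    ct[!ct$gene %in% nps, ]
  })
  inform(sprintf("crosstalk genes: %d", nrow(crosstalk_tab)))
  emit(crosstalk_tab, "crosstalk", "crosstalk.tsv")
  crosstalk <- crosstalk_tab$gene

  # 4. enrichment of crosstalk genes against the supplied sets
  universe <- Reduce(intersect, map(corrected, ~ rownames(.x$matrix)))
  enr <- stage_run("enrichment", {
    if (length(crosstalk)) {
      hypergeometric_enrichment(crosstalk, inputs$pathways, universe)
    } else {
      tibble(set = character(), k = integer(), K = integer(), n = integer(),
             N = integer(), p_value = double(), significant = logical())
    }
  })
  emit(select(enr, -any_of("overlap")), "enrichment", "enrichment.tsv")

  # 5. correlation screen + DRL per disease, cross-disease join
  drl <- stage_run("drl", {
    drl_table(corrected[[1]], corrected[[2]], crosstalk, nps,
              cc_cut = cc_cut, screen_on = screen_on)
  })
  inform(sprintf("screened relationship pairs: %d (%s)",
                 nrow(drl$per_disease),
                 paste(sprintf("%s: %d", diseases,
                               map_int(diseases, ~ sum(drl$per_disease$disease == .x))),
                       collapse = ", ")))
  emit(drl$per_disease, "drl_records", "drl_records.tsv")
  emit(drl$joined, "drl_joined", "drl_joined.tsv")

  # 6. PPI network: direct pairs, one-step bridges, topology
  graph <- stage_run("ppi", ppi_graph(inputs$ppi_edges, crosstalk, nps))
  direct <- direct_pairs(graph)
  bridges <- bridge_pairs(graph)
  inform(sprintf("PPI: %d direct pairs, %d bridge triples",
                 nrow(direct), nrow(bridges$triples)))
  emit(direct, "ppi_direct", "ppi_direct_pairs.tsv")
  emit(bridges$triples, "ppi_bridges", "ppi_bridge_triples.tsv")
  topo <- stage_run("topology", {
    if (igraph::vcount(bridges$subgraph) > 0) {
      topology_metrics(bridges$subgraph)
    } else {
      tibble(node = character(), role = character(), degree = double(),
             avg_shortest_path = double(), betweenness = double(),
             closeness = double(), topological_coefficient = double())
    }
  })
  emit(topo, "topology", "topology.tsv")

  # 7. tripartite crosstalk-pathway-neuropeptide network
  tri <- stage_run("tripartite", {
    shared_pathway_network(crosstalk, nps, inputs$pathways)
  })
  emit(tri, "tripartite", "tripartite.tsv")

  # 8. lasso screening, intersection, ROC / group stats
  screens <- list()
  for (d in diseases) {
    screens[[d]] <- stage_run("lasso", {
      lasso_screen(corrected[[d]], nps, folds = folds, seed = seed,
                   lambda = lasso_lambda, cv_loss = cv_loss,
                   family = lasso_family)
    })
    inform(sprintf("[%s] lasso selected %d panel gene(s)", d,
                   screens[[d]]$n_selected))
  }
  sel_tab <- bind_rows(map(screens, glance))
  emit(bind_rows(map(screens, function(s) {
    tibble(disease = s$disease, gene = s$selected)
  })), "lasso_selected", "lasso_selected.tsv")
  shared_np <- intersect_selected(screens[[1]], screens[[2]])
  inform(sprintf("lasso intersection: %d gene(s)%s", length(shared_np),
                 if (length(shared_np)) paste0(" (", paste(shared_np, collapse = ", "), ")")
                 else ""))
  summary_tab <- stage_run("screen_summary", {
    if (length(shared_np)) {
      bind_rows(map(diseases, ~ screen_summary(corrected[[.x]], shared_np)))
    } else {
      tibble(disease = character(), gene = character(), auc = double())
    }
  })
  emit(summary_tab, "screen_summary", "screen_summary.tsv")

  manifest_tab <- list_rbind(unname(manifest))
  params <- list(
    diseases = diseases,
    thresholds = map(thresholds, unclass),
    cc_cut = cc_cut, screen_on = screen_on,
    lasso_lambda = lasso_lambda, folds = folds, cv_loss = cv_loss,
    lasso_family = lasso_family, batch_correct = batch_correct, seed = seed,
    version = as.character(utils::packageVersion("drlink"))
  )
  jsonlite::write_json(
    list(params = params, manifest = manifest_tab),
    file.path(outdir, "manifest.json"),
    dataframe = "columns", auto_unbox = TRUE, pretty = TRUE
  )

  structure(list(
    corrected = corrected, pca = bind_rows(pca_tabs), degs = degs,
    crosstalk = crosstalk_tab, enrichment = enr, drl = drl,
    ppi = list(graph = graph, direct = direct, bridges = bridges,
               topology = topo),
    tripartite = tri, lasso = screens, lasso_glance = sel_tab,
    lasso_intersection = shared_np, screen_summary = summary_tab,
    manifest = manifest_tab, params = params
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  crosstalk genes: %d\n", nrow(x$crosstalk)))
  cat(sprintf("  DRL records: %d (%d joined across diseases)\n",
              nrow(x$drl$per_disease), nrow(x$drl$joined)))
  cat(sprintf("  PPI: %d direct, %d bridge triples\n",
              nrow(x$ppi$direct), nrow(x$ppi$bridges$triples)))
  cat(sprintf("  lasso intersection: %s\n",
              if (length(x$lasso_intersection))
                paste(x$lasso_intersection, collapse = ", ") else "(none)"))
  invisible(x)
}
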