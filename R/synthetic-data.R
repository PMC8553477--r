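#' Configuration for the synthetic two-disease study
#'
#' Builds the full parameter set for the synthetic-data generator. Defaults
#' emulate the study conditions the pipeline targets: two cohorts sized like
#' the real ones (30/33 case/control across 2 batches; 430/139 across 3
#' batches), a 102-gene neuropeptide panel disjoint from the planted
#' differentially expressed (DE) background, 35 genes DE in both diseases
#' (the planted crosstalk set, 25 up / 10 down), 13 crosstalk-neuropeptide
#' pairs coupled with group-specific slopes, 4 neuropeptides predictive of
#' case status in both diseases, and a background protein-interaction graph
#' with planted crosstalk-bridge-neuropeptide paths.
#'
#' All effects are on the log2 scale. Batch effects follow the additive +
#' multiplicative model the empirical-Bayes correction assumes: per
#' (batch, gene) additive shifts `N(0, batch_shift_sd^2)` and log-normal
#' noise-scale factors with log-sd `batch_scale_sd`. `predictive_shift` is
#' expressed in units of the panel residual SD (`np_noise_sd`).
#'
#' @param seed Integer master seed; every draw derives from it.
#' @param n_genes Background genes (the panel is extra and disjoint).
#' @param n_neuropeptides Panel size.
#' @param diseases Named list (two entries) of per-disease settings; see
#'   defaults for the recognised fields.
#' @param n_crosstalk_planted Genes planted DE in both diseases.
#' @param n_drl_pairs Crosstalk-neuropeptide pairs coupled with slopes
#'   `drl_beta_case` / `drl_beta_control` and residual SD `drl_noise_sd`.
#' @param drl_beta_case,drl_beta_control,drl_noise_sd Coupling parameters.
#' @param n_predictive_np Panel genes given a case-group mean shift.
#' @param predictive_shift Shift in units of `np_noise_sd`.
#' @param np_noise_sd Residual SD of uncoupled panel genes.
#' @param ppi List: `n_other` background nodes, `edge_prob`, `n_planted_bridges`.
#' @param pathways List: `n_sets`, `set_size` (length-2 range), `n_mixed_sets`
#'   (sets forced to contain both a crosstalk gene and a neuropeptide).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_genes = 2000,
                         n_neuropeptides = 102,
                         diseases = list(
                           MDD = list(n_case = 30, n_control = 33, n_batches = 2,
                                      batch_shift_sd = 1, batch_scale_sd = 0.1,
                                      n_de_up = 25, n_de_down = 10,
                                      de_lfc = 2, noise_sd = 1),
                           PD  = list(n_case = 430, n_control = 139, n_batches = 3,
                                      batch_shift_sd = 1, batch_scale_sd = 0.1,
                                      n_de_up = 25, n_de_down = 10,
                                      de_lfc = 2, noise_sd = 1)
                         ),
                         n_crosstalk_planted = 35,
                         n_drl_pairs = 13,
                         drl_beta_case = 1.5,
                         drl_beta_control = -0.5,
                         drl_noise_sd = 0.1,
                         n_predictive_np = 4,
                         predictive_shift = 2,
                         np_noise_sd = 0.2,
                         ppi = list(n_other = 300, edge_prob = 0.01,
                                    n_planted_bridges = 20),
                         pathways = list(n_sets = 30, set_size = c(10, 40),
                                         n_mixed_sets = 5)) {
  cfg <- list(
    seed = as.integer(seed), n_genes = n_genes,
    n_neuropeptides = n_neuropeptides, diseases = diseases,
    n_crosstalk_planted = n_crosstalk_planted, n_drl_pairs = n_drl_pairs,
    drl_beta_case = drl_beta_case, drl_beta_control = drl_beta_control,
    drl_noise_sd = drl_noise_sd, n_predictive_np = n_predictive_np,
    predictive_shift = predictive_shift, np_noise_sd = np_noise_sd,
    ppi = ppi, pathways = pathways
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_neuropeptides, cfg$n_crosstalk_planted,
              cfg$n_drl_pairs, cfg$n_predictive_np,
              cfg$ppi$n_other, cfg$ppi$n_planted_bridges,
              cfg$pathways$n_sets, cfg$pathways$n_mixed_sets)
  if (any(counts < 0)) abort("all counts must be non-negative.")
  if (length(cfg$diseases) != 2 || is.null(names(cfg$diseases))) {
    abort("`diseases` must be a named list with two entries.")
  }
  for (nm in names(cfg$diseases)) {
    d <- cfg$diseases[[nm]]
    if (d$n_case + d$n_control < 4) {
      abort(paste0(nm, ": need at least 4 samples in total."))
    }
    if ((d$n_case + d$n_control) / d$n_batches < 2) {
      abort(paste0(nm, ": a batch would hold fewer than 2 samples."))
    }
    n_de <- d$n_de_up + d$n_de_down
    if (cfg$n_crosstalk_planted > n_de) {
      abort(paste0(nm, ": n_crosstalk_planted exceeds the disease's DE gene count."))
    }
  }
  if (cfg$n_drl_pairs > max(0, cfg$n_neuropeptides - cfg$n_predictive_np)) {
    abort("n_drl_pairs exceeds the number of uncommitted panel genes.")
  }
  if (cfg$n_drl_pairs > 0 && cfg$n_crosstalk_planted == 0) {
    abort("cannot couple panel genes without planted crosstalk genes.")
  }
  if (cfg$n_predictive_np > cfg$n_neuropeptides) {
    abort("n_predictive_np exceeds the panel size.")
  }
  if (cfg$ppi$edge_prob < 0 || cfg$ppi$edge_prob > 1) {
    abort("ppi$edge_prob must lie in [0, 1].")
  }
  invisible(cfg)
}

# Deterministic planted truth shared by every generator call. Every random
# choice here depends only on config$seed, never on which artifact is built
# first, so cohorts, panel and graph are mutually consistent.
plant_truth <- function(cfg) {
  set.seed(cfg$seed)
  genes <- sprintf("GENE%05d", seq_len(cfg$n_genes))
  nps <- sprintf("NP%03d", seq_len(cfg$n_neuropeptides))

  n_up_tot <- map_int(cfg$diseases, ~ as.integer(.x$n_de_up))
  n_dn_tot <- map_int(cfg$diseases, ~ as.integer(.x$n_de_down))
  ct <- sort(sample(genes, cfg$n_crosstalk_planted))
  n_ct_up <- min(min(n_up_tot),
                 round(cfg$n_crosstalk_planted * sum(n_up_tot) /
                         max(1, sum(n_up_tot) + sum(n_dn_tot))))
  n_ct_dn <- cfg$n_crosstalk_planted - n_ct_up
  if (n_ct_dn > min(n_dn_tot)) {
    n_ct_dn <- min(n_dn_tot)
    n_ct_up <- cfg$n_crosstalk_planted - n_ct_dn
  }
  ct_sign <- rep(c(1, -1), c(n_ct_up, n_ct_dn))
  crosstalk <- tibble(gene = ct, sign = ct_sign)

  remaining <- setdiff(genes, ct)
  de <- list()
  for (nm in names(cfg$diseases)) {
    d <- cfg$diseases[[nm]]
    extra_up <- d$n_de_up - n_ct_up
    extra_dn <- d$n_de_down - n_ct_dn
    spec <- sample(remaining, extra_up + extra_dn)
    remaining <- setdiff(remaining, spec)   # disease-specific sets are disjoint
    de[[nm]] <- bind_rows(
      crosstalk,
      tibble(gene = spec, sign = rep(c(1, -1), c(extra_up, extra_dn)))
    ) |> arrange(.data$gene)
  }

  predictive <- if (cfg$n_predictive_np > 0) {
    sort(sample(nps, cfg$n_predictive_np))
  } else character()
  couplable <- setdiff(nps, predictive)
  coupled <- if (cfg$n_drl_pairs > 0) {
    tibble(
      crosstalk = rep_len(crosstalk$gene, cfg$n_drl_pairs),
      neuropeptide = sort(sample(couplable, cfg$n_drl_pairs)),
      beta_case = cfg$drl_beta_case,
      beta_control = cfg$drl_beta_control
    )
  } else {
    tibble(crosstalk = character(), neuropeptide = character(),
           beta_case = double(), beta_control = double())
  }

  list(genes = genes, neuropeptides = nps, crosstalk = crosstalk,
       de = de, predictive = predictive, coupled = coupled)
}

disease_index <- function(cfg, disease) {
  i <- match(disease, names(cfg$diseases))
  if (is.na(i)) {
    abort(paste0("unknown disease '", disease, "'; config defines: ",
                 paste(names(cfg$diseases), collapse = ", ")))
  }
  i
}

#' Generate one synthetic disease cohort (background genes)
#'
#' Log2-scale expression for the background genes of one disease:
#' per-gene baseline `N(7, 1)`, plus `sign * de_lfc` in cases for planted DE
#' genes, plus per-(batch, gene) additive shifts and multiplicative noise
#' scaling, plus i.i.d. Gaussian noise. Batch assignment is round-robin
#' within each group, so batches are balanced across case/control.
#' Fully reproducible from the config seed.
#'
#' @param config A [synth_config()].
#' @param disease One of the names in `config$diseases`.
#' @return A list: `bundle` (an [expression_bundle()] of the background
#'   genes) and `truth` (the planted-truth fragment: DE table for this
#'   disease).
#' @export
generate_disease_cohort <- function(config, disease) {
  validate_synth_config(config)
  i <- disease_index(config, disease)
  d <- config$diseases[[disease]]
  truth <- plant_truth(config)

  n <- d$n_case + d$n_control
  ids <- c(sprintf("%s_case_%03d", disease, seq_len(d$n_case)),
           sprintf("%s_ctrl_%03d", disease, seq_len(d$n_control)))
  group <- rep(c("case", "control"), c(d$n_case, d$n_control))
  batch <- character(n)
  for (g in c("case", "control")) {      # round-robin within group
    idx <- which(group == g)
    batch[idx] <- paste0("batch", rep_len(seq_len(d$n_batches), length(idx)))
  }
  md <- tibble(sample_id = ids, group = group, batch = batch)

  set.seed(config$seed + 1000L * i)
  ng <- config$n_genes
  baseline <- rnorm(ng, mean = 7, sd = 1)
  lfc <- setNames(numeric(ng), truth$genes)
  det <- truth$de[[disease]]
  lfc[det$gene] <- det$sign * d$de_lfc

  mat <- matrix(baseline, ng, n) +
    outer(lfc, as.numeric(group == "case"))
  # batch structure: additive shift and noise-scale per (batch, gene)
  shift <- matrix(rnorm(ng * d$n_batches, 0, d$batch_shift_sd), ng, d$n_batches)
  scale <- matrix(exp(rnorm(ng * d$n_batches, 0, d$batch_scale_sd)), ng, d$n_batches)
  bidx <- as.integer(factor(batch, levels = paste0("batch", seq_len(d$n_batches))))
  noise <- matrix(rnorm(ng * n, 0, d$noise_sd), ng, n)
  mat <- mat + shift[, bidx, drop = FALSE] + scale[, bidx, drop = FALSE] * noise
  dimnames(mat) <- list(truth$genes, ids)

  list(
    bundle = expression_bundle(mat, md, disease = disease),
    truth = list(de = det, crosstalk = truth$crosstalk)
  )
}

#' Generate the neuropeptide panel specification
#'
#' Returns the panel gene list together with the planted coupling
#' specification: which panel genes are linearly coupled to which crosstalk
#' genes (with group-specific slopes) and which panel genes carry a predictive
#' case-group shift. The panel is disjoint from the background genes by
#' construction and no panel gene gets a planted group effect apart from the
#' predictive shift.
#'
#' @param config A [synth_config()].
#' @return A list: `genes` (character), `coupled` (tibble `crosstalk`,
#'   `neuropeptide`, `beta_case`, `beta_control`), `predictive` (character).
#' @export
generate_neuropeptide_panel <- function(config) {
  validate_synth_config(config)
  truth <- plant_truth(config)
  list(genes = truth$neuropeptides, coupled = truth$coupled,
       predictive = truth$predictive)
}

#' Append panel expression rows to a cohort bundle
#'
#' Uncoupled panel genes are baseline plus i.i.d. noise (`np_noise_sd`), and
#' the same batch shift/scale model as the background. Coupled genes follow
#' `y = beta_group * (x - group mean of x) + baseline + noise` with the
#' planted per-group slopes — centering the predictor within group keeps the
#' coupled gene itself non-differentially expressed even though its partner
#' is. Predictive genes additionally get `predictive_shift * np_noise_sd`
#' added in cases. Coupling to a gene outside the planted crosstalk set is
#' rejected.
#'
#' @param cohort Output of [generate_disease_cohort()] (list with `bundle`).
#' @param config The same [synth_config()].
#' @param panel Output of [generate_neuropeptide_panel()]; regenerated from
#'   `config` when omitted.
#' @return An [expression_bundle()] containing background plus panel rows.
#' @export
attach_neuropeptide_panel <- function(cohort, config, panel = NULL) {
  validate_synth_config(config)
  bundle <- cohort$bundle
  panel <- panel %||% generate_neuropeptide_panel(config)
  truth <- plant_truth(config)
  bad <- setdiff(panel$coupled$crosstalk, truth$crosstalk$gene)
  if (length(bad)) {
    abort(paste0("coupling requested to non-planted crosstalk gene(s): ",
                 paste(bad, collapse = ", ")))
  }
  i <- disease_index(config, bundle$disease)
  d <- config$diseases[[bundle$disease]]
  md <- bundle$metadata
  n <- nrow(md)
  np <- length(panel$genes)
  if (np == 0) return(bundle)

  set.seed(config$seed + 1000L * i + 500L)
  baseline <- rnorm(np, mean = 7, sd = 1)
  pmat <- matrix(baseline, np, n) +
    matrix(rnorm(np * n, 0, config$np_noise_sd), np, n)
  dimnames(pmat) <- list(panel$genes, md$sample_id)
  # batch structure, same model as the background
  shift <- matrix(rnorm(np * d$n_batches, 0, d$batch_shift_sd), np, d$n_batches)
  bidx <- as.integer(factor(md$batch,
                            levels = paste0("batch", seq_len(d$n_batches))))
  pmat <- pmat + shift[, bidx, drop = FALSE]

  grp <- as.character(md$group)
  if (nrow(panel$coupled) > 0) {
    for (r in seq_len(nrow(panel$coupled))) {
      pr <- panel$coupled[r, ]
      x <- bundle$matrix[pr$crosstalk, ]
      xc <- x
      for (g in c("case", "control")) {
        xc[grp == g] <- x[grp == g] - mean(x[grp == g])
      }
      beta <- ifelse(grp == "case", pr$beta_case, pr$beta_control)
      pmat[pr$neuropeptide, ] <- rnorm(n, 0, config$drl_noise_sd) +
        baseline[match(pr$neuropeptide, panel$genes)] + beta * xc
    }
  }
  if (length(panel$predictive)) {
    shift_abs <- config$predictive_shift * config$np_noise_sd
    pmat[panel$predictive, grp == "case"] <-
      pmat[panel$predictive, grp == "case"] + shift_abs
  }
  expression_bundle(rbind(bundle$matrix, pmat), md, disease = bundle$disease)
}

#' Generate the synthetic PPI graph and pathway collection
#'
#' Nodes are the crosstalk genes, the panel genes and `ppi$n_other` background
#' genes. Background edges are Erdős–Rényi with probability `edge_prob`,
#' after which any direct crosstalk-neuropeptide edge is removed; then
#' `n_planted_bridges` distinct crosstalk-bridge-neuropeptide paths are wired
#' in through dedicated bridge nodes. Pathway sets are sampled so that exactly
#' `n_mixed_sets` contain at least one gene of each role (the remaining sets
#' exclude crosstalk genes entirely).
#'
#' @param config A [synth_config()].
#' @return A list: `edges` (tibble `from`, `to`), `pathways` (named list of
#'   gene sets), `truth` (list with `bridges` tibble and `mixed_sets`
#'   character).
#' @export
generate_ppi_and_pathways <- function(config) {
  validate_synth_config(config)
  truth <- plant_truth(config)
  ct <- truth$crosstalk$gene
  nps <- truth$neuropeptides
  set.seed(config$seed + 7000L)
  others <- sample(setdiff(truth$genes, ct), config$ppi$n_other)
  nodes <- c(ct, nps, others)
  role <- c(rep("crosstalk", length(ct)), rep("neuropeptide", length(nps)),
            rep("other", length(others)))

  nb <- config$ppi$n_planted_bridges
  if (nb > length(others)) abort("not enough 'other' nodes for the planted bridges.")
  if (nb > 0 && (length(ct) == 0 || length(nps) == 0)) {
    abort("planting bridges requires both crosstalk and neuropeptide nodes.")
  }

  # Erdős–Rényi background
  nn <- length(nodes)
  edges <- NULL
  if (config$ppi$edge_prob > 0) {
    pairs <- which(upper.tri(matrix(TRUE, nn, nn)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < config$ppi$edge_prob
    edges <- tibble(from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]])
    rf <- role[pairs[keep, 1]]; rt <- role[pairs[keep, 2]]
    direct <- (rf == "crosstalk" & rt == "neuropeptide") |
      (rf == "neuropeptide" & rt == "crosstalk")
    edges <- edges[!direct, ]
  } else {
    edges <- tibble(from = character(), to = character())
  }

  bridges <- tibble(crosstalk = character(), bridge = character(),
                    neuropeptide = character())
  if (nb > 0) {
    bridge_nodes <- sample(others, nb)
    bridges <- tibble(
      crosstalk = sample(ct, nb, replace = TRUE),
      bridge = bridge_nodes,
      neuropeptide = sample(nps, nb, replace = TRUE)
    )
    # remove any background edge touching a dedicated bridge node so the
    # planted path count is exact when edge_prob = 0 and near-exact otherwise
    edges <- edges |>
      filter(!.data$from %in% bridge_nodes, !.data$to %in% bridge_nodes)
    edges <- bind_rows(
      edges,
      tibble(from = bridges$crosstalk, to = bridges$bridge),
      tibble(from = bridges$bridge, to = bridges$neuropeptide)
    )
  }
  edges <- distinct(edges)

  pw <- config$pathways
  sizes <- sample(seq(pw$set_size[1], pw$set_size[2]), pw$n_sets, replace = TRUE)
  non_crosstalk_pool <- c(setdiff(truth$genes, ct), nps)
  pathways <- list()
  for (s in seq_len(pw$n_sets)) {
    name <- sprintf("PATHWAY_%03d", s)
    if (s <= pw$n_mixed_sets) {
      k_ct <- sample(1:min(3, length(ct)), 1)
      k_np <- sample(1:min(3, length(nps)), 1)
      rest <- max(0, sizes[s] - k_ct - k_np)
      pathways[[name]] <- sort(unique(c(
        sample(ct, k_ct), sample(nps, k_np),
        sample(setdiff(truth$genes, ct), rest)
      )))
    } else {
      pathways[[name]] <- sort(unique(sample(non_crosstalk_pool, sizes[s])))
    }
  }
  mixed <- names(pathways)[seq_len(pw$n_mixed_sets)]

  list(edges = edges, pathways = pathways,
       truth = list(bridges = bridges, mixed_sets = mixed,
                    nodes = tibble(node = nodes, role = role)))
}

#' Simulate the complete synthetic study
#'
#' Orchestrates the cohort, panel and network generators into one consistent
#' study object with its truth ledger.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_study`: `bundles` (named list of two
#'   [expression_bundle()]s, background + panel rows), `neuropeptides`,
#'   `ppi_edges`, `pathways`, `config`, and `truth` (planted DE per disease,
#'   crosstalk set, coupled pairs, predictive panel genes, bridge triples,
#'   mixed pathway ids).
#' @export
simulate_study <- function(config = synth_config()) {
  validate_synth_config(config)
  panel <- generate_neuropeptide_panel(config)
  truth <- plant_truth(config)
  bundles <- list()
  for (nm in names(config$diseases)) {
    cohort <- generate_disease_cohort(config, nm)
    bundles[[nm]] <- attach_neuropeptide_panel(cohort, config, panel)
  }
  net <- generate_ppi_and_pathways(config)
  structure(list(
    bundles = bundles,
    neuropeptides = panel$genes,
    ppi_edges = net$edges,
    pathways = net$pathways,
    config = config,
    truth = list(
      de = truth$de, crosstalk = truth$crosstalk,
      coupled = truth$coupled, predictive = truth$predictive,
      bridges = net$truth$bridges, mixed_sets = net$truth$mixed_sets,
      nodes = net$truth$nodes
    )
  ), class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("<synth_study>\n")
  for (nm in names(x$bundles)) print(x$bundles[[nm]])
  cat(sprintf("  panel: %d genes (%d coupled pairs, %d predictive)\n",
              length(x$neuropeptides), nrow(x$truth$coupled),
              length(x$truth$predictive)))
  cat(sprintf("  ppi: %d edges; pathways: %d sets (%d mixed)\n",
              nrow(x$ppi_edges), length(x$pathways),
              length(x$truth$mixed_sets)))
  invisible(x)
}

#' Write a ready-to-run synthetic study to disk
#'
#' Materializes [simulate_study()] as plain-text inputs: per-disease
#' expression/metadata TSVs, the panel gene list (one symbol per line), the
#' pathway GMT, the PPI edge list TSV, the truth ledger as JSON and the
#' generating configuration as YAML.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master seed.
#' @param config Optional [synth_config()]; overrides `seed` when given.
#' @return Invisibly, a list with the study object and the file paths.
#' @export
make_demo <- function(outdir, seed = 1, config = NULL) {
  config <- config %||% synth_config(seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) abort(paste0("cannot write to ", outdir))
  study <- simulate_study(config)
  paths <- list()
  for (nm in names(study$bundles)) {
    stem <- file.path(outdir, tolower(nm))
    paths[[nm]] <- write_bundle_tsv(study$bundles[[nm]], stem)
  }
  np_path <- file.path(outdir, "neuropeptides.txt")
  writeLines(study$neuropeptides, np_path)
  gmt_path <- file.path(outdir, "pathways.gmt")
  write_gmt(study$pathways, gmt_path)
  ppi_path <- file.path(outdir, "ppi_edges.tsv")
  readr::write_tsv(study$ppi_edges, ppi_path)
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(
    list(
      de = study$truth$de, crosstalk = study$truth$crosstalk,
      coupled = study$truth$coupled, predictive = study$truth$predictive,
      bridges = study$truth$bridges, mixed_sets = study$truth$mixed_sets
    ),
    truth_path, dataframe = "columns", pretty = TRUE
  )
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  invisible(list(study = study, paths = c(
    paths, list(neuropeptides = np_path, gmt = gmt_path, ppi = ppi_path,
                truth = truth_path, config = cfg_path)
  )))
}
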