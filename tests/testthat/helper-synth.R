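# Small study configurations used across tests. Sizes are scaled down from
# the package defaults so the whole suite stays fast; effect sizes keep the
# default magnitudes.

tiny_config <- function(seed = 1, ...) {
  base <- list(
    seed = seed,
    n_genes = 300,
    n_neuropeptides = 30,
    diseases = list(
      MDD = list(n_case = 30, n_control = 33, n_batches = 2,
                 batch_shift_sd = 1, batch_scale_sd = 0.1,
                 n_de_up = 8, n_de_down = 4, de_lfc = 2, noise_sd = 1),
      PD = list(n_case = 60, n_control = 40, n_batches = 2,
                batch_shift_sd = 1, batch_scale_sd = 0.1,
                n_de_up = 8, n_de_down = 4, de_lfc = 2, noise_sd = 1)
    ),
    n_crosstalk_planted = 10,
    n_drl_pairs = 4,
    n_predictive_np = 2,
    np_noise_sd = 0.2,
    ppi = list(n_other = 60, edge_prob = 0.02, n_planted_bridges = 5),
    pathways = list(n_sets = 8, set_size = c(5, 15), n_mixed_sets = 3)
  )
  do.call(synth_config, utils::modifyList(base, list(...)))
}

# a deterministic little bundle built by hand: 2 groups x known values
toy_bundle <- function(mat, groups, batches = NULL, disease = "toy") {
  n <- ncol(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(n))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("G", seq_len(nrow(mat)))
  md <- tibble::tibble(
    sample_id = colnames(mat),
    group = groups,
    batch = batches %||% rep("b1", n)
  )
  expression_bundle(mat, md, disease = disease)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
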