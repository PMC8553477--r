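# bundle with two groups of 5 whose values are set directly per gene
pair_bundle <- function(x_case, y_case, x_ctrl, y_ctrl) {
  m <- rbind(CT = c(x_case, x_ctrl), NP = c(y_case, y_ctrl))
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  toy_bundle(m, rep(c("case", "control"), c(length(x_case), length(x_ctrl))))
}

test_that("pairwise correlation reproduces hand-computed Pearson values", {
  x <- c(1, 2, 3, 4, 5)
  b <- pair_bundle(x, 2 * x + 1, x, -x)
  ids_case <- paste0("S", 1:5); ids_ctrl <- paste0("S", 6:10)
  expect_equal(pairwise_correlation(b, "CT", "NP", ids_case)$r, 1.0)
  expect_equal(pairwise_correlation(b, "CT", "NP", ids_ctrl)$r, -1.0)

  b2 <- pair_bundle(c(1, 2, 3), c(1, 3, 2), c(1, 2, 3), c(0, 0, 1))
  expect_equal(pairwise_correlation(b2, "CT", "NP", paste0("S", 1:3))$r, 0.5,
               tolerance = 1e-12)
  expect_error(pairwise_correlation(b2, "CT", "NP", paste0("S", 1:2)), "3 samples")
  expect_error(pairwise_correlation(b2, "ZZ", "NP"), "absent")
})

test_that("zero-variance genes give NA correlations with a warning", {
  b <- pair_bundle(rep(2, 4), 1:4, 1:4, 1:4)
  expect_warning(
    pc <- pairwise_correlation(b, "CT", "NP", paste0("S", 1:4)),
    "zero-variance"
  )
  expect_true(is.na(pc$r))
  # and screening drops the pair
  cors <- tibble::tibble(gene_a = "CT", gene_b = "NP",
                         cc_case = NA_real_, cc_control = 0.9, cc_all = 0.9)
  expect_equal(nrow(screen_pairs(cors)), 0)
})

test_that("the |r| cutoff is strict and applied to absolute values", {
  cors <- tibble::tibble(
    gene_a = c("a", "b", "c"), gene_b = "n",
    cc_case = c(0.5, -0.51, 0.49), cc_control = 0, cc_all = 0
  )
  kept <- screen_pairs(cors, cc_cut = 0.5)
  expect_equal(kept$gene_a, "b")
  # screening column switch
  cors$cc_all <- c(0.9, 0, 0)
  expect_equal(screen_pairs(cors, screen_on = "all")$gene_a, "a")
})

test_that("per-group OLS matches closed-form hand computation", {
  # perfect line in cases: beta 3, intercept -1, zero slope SE
  x <- c(0, 1, 2, 3, 4)
  b <- pair_bundle(x, 3 * x - 1, c(0, 1, 2, 1, 0), c(0, 1, 1, 1, 0))
  reg <- fit_group_regressions(b, "CT", "NP")
  rc <- reg[reg$group == "case", ]
  expect_equal(rc$beta, 3, tolerance = 1e-12)
  expect_equal(rc$beta0, -1, tolerance = 1e-12)
  expect_equal(rc$sd, 0)

  # x=[0,1,2], y=[0,1,1]: beta 1/2, beta0 1/6, sd = sqrt(1/12)
  b2 <- pair_bundle(c(0, 1, 2), c(0, 1, 1), c(0, 1, 2), c(5, 5, 6))
  reg2 <- fit_group_regressions(b2, "CT", "NP")
  rc2 <- reg2[reg2$group == "case", ]
  expect_equal(rc2$beta, 0.5, tolerance = 1e-12)
  expect_equal(rc2$beta0, 1 / 6, tolerance = 1e-12)
  expect_equal(rc2$sd, sqrt(1 / 12), tolerance = 1e-12)

  # against lm() as an independent oracle on random data
  set.seed(4)
  b3 <- pair_bundle(rnorm(20), rnorm(20), rnorm(20), rnorm(20))
  reg3 <- fit_group_regressions(b3, "CT", "NP")
  grp <- b3$metadata$group
  for (g in c("case", "control")) {
    f <- lm(b3$matrix["NP", grp == g] ~ b3$matrix["CT", grp == g])
    expect_equal(reg3$beta[reg3$group == g], unname(coef(f)[2]), tolerance = 1e-10)
    expect_equal(reg3$sd[reg3$group == g],
                 unname(summary(f)$coefficients[2, 2]), tolerance = 1e-10)
  }

  bconst <- pair_bundle(rep(1, 3), 1:3, 1:3, 1:3)
  expect_error(fit_group_regressions(bconst, "CT", "NP"), "constant in the case")
})

test_that("the DRL formula evaluates correctly and matches its oracle", {
  expect_equal(compute_drl(2, 2, 1, 1, 0), 0)
  expect_equal(compute_drl(2, 1, 1, 1, 0.5), 1 / sqrt(2) + 0.5, tolerance = 1e-12)
  set.seed(10)
  n <- 100
  bc <- rnorm(n); bn <- rnorm(n)
  sc <- runif(n, 0.01, 2); sn <- runif(n, 0.01, 2); cc <- runif(n, -1, 1)
  expect_equal(compute_drl(bc, bn, sc, sn, cc), drl_oracle(bc, bn, sc, sn, cc),
               tolerance = 1e-12)
  expect_error(compute_drl(1, 0, 0, 0, 0.2), "both zero|undefined")
  expect_error(compute_drl(1, 0, -1, 1, 0), ">= 0")
  expect_equal(drl_sign_class(c(2, -0.1, 0)), c("consistent", "opposite", "zero"))
})

test_that("swapping group labels negates the slope contrast, not cc_all", {
  set.seed(5)
  x1 <- rnorm(10); y1 <- 1.5 * x1 + rnorm(10, 0, 0.3)
  x2 <- rnorm(10); y2 <- -0.5 * x2 + rnorm(10, 0, 0.3)
  b <- pair_bundle(x1, y1, x2, y2)
  swapped <- b
  swapped$metadata$group <- factor(
    ifelse(b$metadata$group == "case", "control", "case"),
    levels = c("control", "case")
  )
  r1 <- fit_group_regressions(b, "CT", "NP")
  r2 <- fit_group_regressions(swapped, "CT", "NP")
  term <- function(r) {
    (r$beta[r$group == "case"] - r$beta[r$group == "control"]) /
      sqrt(sum(r$sd^2))
  }
  expect_equal(term(r1), -term(r2), tolerance = 1e-12)
  cc_all1 <- pairwise_correlation(b, "CT", "NP")$r
  cc_all2 <- pairwise_correlation(swapped, "CT", "NP")$r
  expect_equal(cc_all1, cc_all2)
})

test_that("rescaling the response leaves the slope-contrast term invariant", {
  set.seed(6)
  x1 <- rnorm(12); y1 <- 2 * x1 + rnorm(12, 0, 0.5)
  x2 <- rnorm(12); y2 <- -x2 + rnorm(12, 0, 0.5)
  b <- pair_bundle(x1, y1, x2, y2)
  c_scale <- 3.7
  b2 <- b
  b2$matrix["NP", ] <- c_scale * b2$matrix["NP", ]
  r1 <- fit_group_regressions(b, "CT", "NP")
  r2 <- fit_group_regressions(b2, "CT", "NP")
  expect_equal(r2$beta, c_scale * r1$beta, tolerance = 1e-10)
  expect_equal(r2$sd, c_scale * r1$sd, tolerance = 1e-10)
  term <- function(r) diff(rev(r$beta)) / sqrt(sum(r$sd^2))
  expect_equal(term(r1), term(r2), tolerance = 1e-10)
})

test_that("drl_records recovers planted couplings with the right sign", {
  cfg <- tiny_config(seed = 12, n_drl_pairs = 3)
  cfg$diseases$MDD <- utils::modifyList(
    cfg$diseases$MDD,
    list(n_case = 50, n_control = 50, n_batches = 1, batch_shift_sd = 0)
  )
  cohort <- generate_disease_cohort(cfg, "MDD")
  full <- attach_neuropeptide_panel(cohort, cfg)
  truth <- drlink:::plant_truth(cfg)
  rec <- drl_records(full, truth$crosstalk$gene, truth$neuropeptides)
  planted <- dplyr::inner_join(rec, truth$coupled,
                               by = c("crosstalk", "neuropeptide"),
                               suffix = c("", "_truth"))
  expect_equal(nrow(planted), 3)
  # beta_case > beta_control was planted, so the slope contrast is positive
  expect_true(all(planted$beta_case > planted$beta_control))
  expect_equal(planted$beta_case, planted$beta_case_truth, tolerance = 0.15)
  # oracle recomputation of every reported DRL
  expect_equal(rec$drl,
               drl_oracle(rec$beta_case, rec$beta_control,
                          rec$sd_case, rec$sd_control, rec$cc_all),
               tolerance = 1e-12)
  expect_equal(rec$sign_class, drl_sign_class(rec$drl))
})

test_that("drl_table joins records across diseases and survives empties", {
  cfg <- tiny_config(seed = 13)
  study <- simulate_study(cfg)
  tab <- drl_table(study$bundles$MDD, study$bundles$PD,
                   study$truth$crosstalk$gene, study$neuropeptides)
  expect_true(all(c("drl_MDD", "drl_PD") %in% names(tab$joined)))
  expect_true(all(tab$joined$crosstalk %in% study$truth$crosstalk$gene))
  # no crosstalk genes at all: empty but well-formed
  empty <- drl_table(study$bundles$MDD, study$bundles$PD,
                     character(), study$neuropeptides)
  expect_equal(nrow(empty$per_disease), 0)
  expect_equal(nrow(empty$joined), 0)
})
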