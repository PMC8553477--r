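md2 <- function(n, groups = NULL) {
  tibble::tibble(sample_id = paste0("S", seq_len(n)),
                 group = groups %||% rep(c("case", "control"), length.out = n),
                 batch = "b1")
}

test_that("collapse_probes averages probes per gene and drops unmapped", {
  pm <- matrix(c(2, 4, 4, 6, 9, 9), nrow = 3, byrow = TRUE,
               dimnames = list(c("p1", "p2", "p3"), c("S1", "S2")))
  map <- tibble::tibble(probe_id = c("p1", "p2", "p4"), symbol = c("g", "g", "h"))
  b <- collapse_probes(pm, map, md2(2))
  expect_equal(rownames(b$matrix), "G")      # p3 unmapped, dropped; upper-cased
  expect_equal(unname(b$matrix["G", ]), c(3, 5))

  # single-probe gene passes through unchanged
  map2 <- tibble::tibble(probe_id = c("p1", "p3"), symbol = c("a", "b"))
  b2 <- collapse_probes(pm, map2, md2(2))
  expect_equal(unname(b2$matrix["B", ]), c(9, 9))

  # hand mean of three probes in one sample
  pm3 <- matrix(c(1, 2, 6), 3, 1, dimnames = list(paste0("q", 1:3), "S1"))
  pm3 <- cbind(pm3, S2 = c(0, 0, 0))
  map3 <- tibble::tibble(probe_id = paste0("q", 1:3), symbol = "x")
  b3 <- collapse_probes(pm3, map3, md2(2))
  expect_equal(unname(b3$matrix["X", "S1"]), 3)

  expect_error(collapse_probes(pm, map[0, ], md2(2)), "empty")
  map_none <- tibble::tibble(probe_id = "zz", symbol = "g")
  expect_error(collapse_probes(pm, map_none, md2(2)), "no probe")
})

test_that("merge_datasets intersects genes and concatenates samples", {
  m1 <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  m2 <- matrix(2, 3, 2, dimnames = list(c("B", "C", "D"), c("T1", "T2")))
  b1 <- toy_bundle(m1, c("case", "control"))
  b2 <- toy_bundle(m2, c("case", "control"))
  merged <- merge_datasets(list(d1 = b1, d2 = b2))
  expect_equal(rownames(merged$matrix), c("B", "C"))
  expect_equal(ncol(merged$matrix), 4)
  expect_equal(merged$metadata$batch, c("d1", "d1", "d2", "d2"))

  # one bundle: unchanged apart from the batch label
  single <- merge_datasets(list(only = b1))
  expect_equal(single$matrix, b1$matrix[sort(rownames(b1$matrix)), ])
  expect_true(all(single$metadata$batch == "only"))

  m3 <- matrix(3, 2, 2, dimnames = list(c("X", "Y"), c("U1", "U2")))
  b3 <- toy_bundle(m3, c("case", "control"))
  expect_error(merge_datasets(list(b1, b3)), "intersection")
})

test_that("sample ids colliding across datasets get prefixed", {
  m <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  b1 <- toy_bundle(m, c("case", "control"))
  b2 <- toy_bundle(m + 1, c("case", "control"))
  merged <- merge_datasets(list(x = b1, y = b2))
  expect_setequal(merged$metadata$sample_id, c("x_S1", "x_S2", "y_S1", "y_S2"))
})

test_that("collapse then merge agrees with merge then collapse on shared genes", {
  set.seed(1)
  pm1 <- matrix(rnorm(8), 4, 2,
                dimnames = list(paste0("p", 1:4), c("S1", "S2")))
  pm2 <- matrix(rnorm(8), 4, 2,
                dimnames = list(paste0("p", 1:4), c("T1", "T2")))
  map <- tibble::tibble(probe_id = paste0("p", 1:4), symbol = c("a", "a", "b", "c"))
  meta1 <- md2(2); meta2 <- tibble::tibble(sample_id = c("T1", "T2"),
                                           group = c("case", "control"),
                                           batch = "b1")
  route1 <- merge_datasets(list(
    d1 = collapse_probes(pm1, map, meta1),
    d2 = collapse_probes(pm2, map, meta2)
  ))
  # same platform in both datasets: collapse the concatenated probe matrix
  pmc <- cbind(pm1, pm2)
  route2 <- collapse_probes(pmc, map, dplyr::bind_rows(meta1, meta2))
  expect_equal(route1$matrix, route2$matrix[rownames(route1$matrix), ])
})

test_that("cohort-size bookkeeping adds up across merged datasets", {
  mk <- function(n_case, n_control, stem) {
    n <- n_case + n_control
    m <- matrix(rnorm(5 * n), 5, n,
                dimnames = list(paste0("G", 1:5), paste0(stem, seq_len(n))))
    toy_bundle(m, rep(c("case", "control"), c(n_case, n_control)))
  }
  pd <- merge_datasets(list(gA = mk(183, 64, "a"), gB = mk(241, 69, "b"),
                            gC = mk(3, 3, "c")))
  expect_equal(ncol(pd$matrix), 563)
  expect_equal(sum(pd$metadata$group == "case"), 427)
  expect_equal(sum(pd$metadata$group == "control"), 136)
  mdd <- merge_datasets(list(gA = mk(9, 9, "a"), gB = mk(21, 24, "b")))
  expect_equal(ncol(mdd$matrix), 63)
})

test_that("single-batch input is returned unchanged with a warning", {
  set.seed(2)
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:10)))
  b <- toy_bundle(m, rep(c("case", "control"), 5))
  expect_warning(out <- combat_adjust(b), "single batch")
  expect_identical(out$matrix, b$matrix)
})

test_that("a pure constant batch shift is removed almost exactly", {
  # deterministic within-batch pattern, identical across batches; batch 2 is
  # shifted by a constant. Location-only correction must cancel the shift.
  set.seed(1)
  shift <- 5
  pattern <- rep(c(-1, 0, 1, 2), length.out = 8)
  m <- matrix(rep(1:6, 16), 6, 16) +
    matrix(rep(c(pattern, pattern), each = 6), 6, 16)
  m[, 9:16] <- m[, 9:16] + shift
  # numerically negligible jitter keeps the across-gene prior fits
  # non-degenerate without adding meaningful noise
  m <- m + matrix(rnorm(96, 0, 1e-8), 6, 16)
  dimnames(m) <- list(paste0("G", 1:6), paste0("S", 1:16))
  b <- toy_bundle(m, rep(c("case", "control"), 8),
                  batches = rep(c("b1", "b2"), each = 8))
  adj <- combat_adjust(b, protect_group = FALSE)
  diff <- rowMeans(adj$matrix[, 1:8]) - rowMeans(adj$matrix[, 9:16])
  expect_true(all(abs(diff) < 1e-6 * shift))
})

test_that("batch correction keeps dimensions and per-gene grand means", {
  cfg <- tiny_config(seed = 8)
  study <- simulate_study(cfg)
  b <- study$bundles$MDD
  adj <- combat_adjust(b)
  expect_equal(dim(adj$matrix), dim(b$matrix))
  expect_lt(max(abs(rowMeans(adj$matrix) - rowMeans(b$matrix))), 0.05)
})

test_that("group-confounded batches are rejected when protecting group", {
  set.seed(3)
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:10)))
  b <- toy_bundle(m, rep(c("case", "control"), each = 5),
                  batches = rep(c("b1", "b2"), each = 5))
  expect_error(combat_adjust(b, protect_group = TRUE), "confounded")
})

test_that("pca_scores matches an independent eigendecomposition", {
  m <- matrix(c(1, 4, 2, 7, 3, 5, 2, 8, 1), 3, 3,
              dimnames = list(paste0("G", 1:3), paste0("S", 1:3)))
  b <- toy_bundle(m, c("case", "case", "control"))
  sc <- pca_scores(b, k = 2)
  centered <- m - rowMeans(m)
  x <- t(centered)                          # samples x genes
  eig <- eigen(crossprod(x))                # gene-space scatter matrix
  for (j in 1:2) {
    ours <- sc[[paste0("PC", j)]]
    theirs <- as.vector(x %*% eig$vectors[, j])
    agree <- min(max(abs(ours - theirs)), max(abs(ours + theirs)))
    expect_lt(agree, 1e-8)
  }
  ev <- attr(sc, "explained")
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-12)
})

test_that("pca detects duplicate samples and rank-1 structure", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, 4, 5, 6, 4, 5, 6), 3, 4,
              dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
  b <- toy_bundle(m, c("case", "case", "control", "control"))
  sc <- pca_scores(b, k = 2)
  expect_equal(sc$PC1[1], sc$PC1[2])
  expect_equal(sc$PC1[3], sc$PC1[4])
  # rank-1: first component carries all variance
  ev <- attr(sc, "explained")
  expect_equal(ev[1], 1, tolerance = 1e-12)
  expect_error(pca_scores(b, k = 0), "positive")
})
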