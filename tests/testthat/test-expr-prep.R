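test_that("TPM conversion normalizes length-corrected rates to one million", {
  # single gene: any count and length collapse to 1e6
  m1 <- counts_fixture(matrix(7, 1, 1))
  expect_equal(unname(counts_to_tpm(m1, c(g01 = 500))$values[1, 1]), 1e6)

  # equal counts and lengths split evenly
  m2 <- counts_fixture(matrix(c(10, 10), 2, 1))
  tpm2 <- counts_to_tpm(m2, c(g01 = 1000, g02 = 1000))
  expect_equal(unname(tpm2$values[, 1]), c(5e5, 5e5))

  # hand-evaluated case: rates 10/1 and 20/4 = 5 -> 2/3 and 1/3 of 1e6
  m3 <- counts_fixture(matrix(c(10, 20), 2, 1))
  tpm3 <- counts_to_tpm(m3, c(g01 = 1000, g02 = 4000))
  expect_equal(unname(tpm3$values[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  expect_error(counts_to_tpm(m3, c(g01 = 1000)), "g02")
  expect_error(counts_to_tpm(counts_to_cpm(m3)), "state")
})

test_that("CPM columns sum to one million and zero spots are preserved", {
  m <- counts_fixture(matrix(c(1, 1, 2), 3, 1))
  expect_equal(unname(counts_to_cpm(m)$values[, 1]), c(250000, 250000, 500000))

  mz <- counts_fixture(cbind(c(1, 2, 3), c(0, 0, 0)))
  cz <- counts_to_cpm(mz)
  expect_equal(unname(cz$values[, 2]), c(0, 0, 0))
  expect_equal(unname(cz$zero_cols), c(FALSE, TRUE))

  # random matrices against the per-column oracle
  set.seed(42)
  for (rep in 1:5) {
    v <- matrix(rpois(100, 5), 20, 5)
    m <- counts_fixture(v)
    cpm <- counts_to_cpm(m)$values
    oracle <- apply(v, 2, function(col) col / sum(col) * 1e6)
    expect_equal(unname(cpm), oracle, tolerance = 1e-12)
    expect_true(all(abs(colSums(cpm) - 1e6) < 1e-3 * 1e6))
  }
})

test_that("TPM column sums hit one million on random inputs", {
  set.seed(7)
  v <- matrix(rpois(60, 8), 12, 5)
  lens <- setNames(sample(200:5000, 12), sprintf("g%02d", 1:12))
  tpm <- counts_to_tpm(counts_fixture(v), lens)$values
  expect_true(all(abs(colSums(tpm) / 1e6 - 1) < 1e-3))
})

test_that("pseudo-bulk is the CPM of summed spot counts", {
  # one spot: identical to its own CPM
  m1 <- counts_fixture(matrix(c(3, 9), 2, 1))
  expect_equal(unname(make_pseudobulk(m1)),
               unname(counts_to_cpm(m1)$values[, 1]))

  # duplicated spots: CPM is scale invariant
  m2 <- counts_fixture(cbind(c(4, 6), c(4, 6)))
  expect_equal(unname(make_pseudobulk(m2)),
               unname(counts_to_cpm(m1)$values[, 1] * 0 +
                        c(4, 6) / 10 * 1e6))

  # random matrix vs the row-sum oracle
  set.seed(11)
  v <- matrix(rpois(240, 4), 30, 8)
  pb <- make_pseudobulk(counts_fixture(v))
  oracle <- rowSums(v) / sum(v) * 1e6
  expect_equal(unname(pb), oracle, tolerance = 1e-12)
  expect_equal(sum(pb), 1e6)

  # invariant to spot order
  perm <- sample(8)
  expect_equal(make_pseudobulk(counts_fixture(v[, perm])), pb)
})

test_that("log transform is log2(v+1) with exact inverse", {
  m <- counts_fixture(matrix(c(0, 1, 3), 3, 1))
  lg <- log_transform(counts_to_cpm(m))
  expect_equal(lg$state, "log2p1")
  # fixed points of the map itself
  v <- expr_matrix(matrix(c(0, 1, 3), 3, 1,
                          dimnames = list(c("a", "b", "c"), "s")), "cpm")
  expect_equal(unname(log_transform(v)$values[, 1]), c(0, 1, 2))

  set.seed(3)
  x <- matrix(runif(50, 0, 20), 10, 5,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:5)))
  lt <- log_transform(expr_matrix(x, "cpm"))
  expect_equal(2^lt$values - 1, x, tolerance = 1e-9)

  expect_error(log_transform(counts_fixture(matrix(1, 1, 1))), "state")
})

test_that("spot filtering keeps spots with at least min_genes detected", {
  v <- matrix(0, 120, 3)
  v[1:100, 1] <- 1   # exactly 100 detected -> kept
  v[1:99, 2] <- 1    # 99 detected -> dropped
  v[1:120, 3] <- 1
  kept <- filter_spots(counts_fixture(v), min_genes = 100)
  expect_equal(colnames(kept$values), c("s01", "s03"))

  none <- filter_spots(counts_fixture(v), min_genes = 121)
  expect_equal(ncol(none$values), 0)
})

test_that("protein-coding restriction preserves order and rejects empty sets", {
  m <- counts_fixture(matrix(1:20, 10, 2))
  expect_equal(restrict_to_protein_coding(m, gene_ids <- rownames(m$values))$values,
               m$values)
  sub <- restrict_to_protein_coding(m, c("g07", "g02", "g04", "g09"))
  expect_equal(rownames(sub$values), c("g02", "g04", "g07", "g09"))
  expect_error(restrict_to_protein_coding(m, character(0)), "no genes")
})

test_that("target-gene selection recovers planted image-associated genes", {
  set.seed(5)
  n_b <- 40; n_s <- 60; d <- 6
  fb <- matrix(rnorm(n_b * d), n_b, d)
  fs <- matrix(rnorm(n_s * d), n_s, d)
  G <- 50; planted <- 1:10
  mk <- function(feat, n) {
    v <- matrix(rnorm(n * G, mean = 6, sd = 1), n, G)
    for (g in planted) v[, g] <- 6 + feat[, (g %% d) + 1] + rnorm(n, sd = 0.1)
    t(pmax(v, 0))  # genes x samples
  }
  vb <- mk(fb, n_b); vs <- mk(fs, n_s)
  rownames(vb) <- rownames(vs) <- sprintf("g%02d", 1:G)
  colnames(vb) <- sprintf("b%02d", 1:n_b); colnames(vs) <- sprintf("s%02d", 1:n_s)
  bulk <- expr_matrix(vb, "log2p1")
  spot <- expr_matrix(vs, "log2p1")
  sel <- select_target_genes(bulk, fb, spot, fs, K = 10)
  expect_setequal(sel$gene_id[sel$selected], sprintf("g%02d", planted))
  # perfect-correlation gene sits at rank 1 on both levels
  top <- sel[1, ]
  expect_true(top$score_bulk > 0.9 && top$score_spot > 0.9)

  expect_error(select_target_genes(bulk, fb, spot, fs, K = 51), "exceeds")
})

test_that("selection tie-break is lexicographic and input-order invariant", {
  # two identical genes -> identical scores; lexicographic order decides
  set.seed(8)
  f <- matrix(rnorm(20), 10, 2)
  base <- 6 + f[, 1] + rnorm(10, sd = 0.01)
  v <- rbind(zzz = base, aaa = base, mid = rnorm(10, mean = 6))
  colnames(v) <- sprintf("s%d", 1:10)
  em <- expr_matrix(pmax(v, 0), "log2p1")
  sel <- select_target_genes(em, f, em, f, K = 2)
  expect_equal(sel$gene_id[sel$selected], c("aaa", "zzz"))

  em2 <- expr_matrix(em$values[c(2, 3, 1), ], "log2p1")
  sel2 <- select_target_genes(em2, f, em2, f, K = 2)
  expect_equal(sel2$gene_id[sel2$selected], sel$gene_id[sel$selected])
})
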