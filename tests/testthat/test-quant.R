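toy_table <- function(counts, lib = NULL, batches = NULL) {
  if (is.null(lib)) lib <- stats::setNames(rep(1e6, ncol(counts)), colnames(counts))
  if (is.null(batches)) {
    batches <- data.frame(dataset_id = colnames(counts), species = "bta",
                          tissue = "liver", batch_id = "b1",
                          stringsAsFactors = FALSE)
  }
  expression_table(counts, lib, batches)
}

test_that("per-million scaling is exact and homogeneous", {
  expect_equal(per_million(500, 5e7), 10)
  expect_equal(per_million(0, 5e7), 0)
  expect_equal(per_million(1000, 1e8), per_million(500, 5e7))
  expect_error(per_million(5, 0), "positive")
})

test_that("TMM factors are unit for identical columns and undo depth", {
  set.seed(9)
  base <- rnbinom(300, mu = 40, size = 3)
  m <- cbind(a = base, b = base)
  f <- tmm_factors(m)
  expect_equal(unname(f), c(1, 1))

  m2 <- cbind(a = base, b = 2L * base)
  f2 <- tmm_factors(m2)
  # a pure depth difference is absorbed by library size x factor
  eff <- colSums(m2) * f2
  norm <- sweep(m2, 2, eff, "/")
  expect_equal(norm[, "a"], norm[, "b"])
  expect_error(tmm_factors(cbind(a = base, z = 0L * base)), "z")
})

test_that("TMM matches the independent trimmed-mean-of-M oracle to 1e-6", {
  set.seed(40)
  for (rep in 1:8) {
    m <- matrix(rnbinom(800, mu = exp(runif(1, 2, 5)), size = runif(1, 0.5, 5)),
                200, 4, dimnames = list(NULL, paste0("d", 1:4)))
    if (any(colSums(m) == 0)) next
    lib <- colSums(m)
    expect_equal(tmm_factors(m), tmm_oracle(m, lib), tolerance = 1e-6)
  }
})

test_that("batch expression averages normalized columns, order-invariantly", {
  set.seed(10)
  counts <- matrix(rnbinom(120, mu = 30, size = 5), 20, 6,
                   dimnames = list(sprintf("c%02d", 1:20), sprintf("d%d", 1:6)))
  counts[3, ] <- 0  # absent circRNA stays 0
  batches <- data.frame(dataset_id = colnames(counts), species = "bta",
                        tissue = "liver",
                        batch_id = rep(c("b1", "b2", "b_single"), c(3, 2, 1)),
                        stringsAsFactors = FALSE)
  lib <- stats::setNames(runif(6, 1e7, 3e7), colnames(counts))
  tab <- toy_table(counts, lib, batches)

  f <- tmm_factors(tab)
  b1 <- batch_expression(tab, "b1", f)
  expect_equal(unname(b1["c03"]), 0)
  # single-dataset batch is that normalized column
  single <- batch_expression(tab, "b_single", f)
  expect_equal(single,
               counts[, "d6"] * 1e6 / (lib["d6"] * f["d6"]),
               ignore_attr = TRUE)
  # permuting dataset columns changes nothing
  perm <- sample(6)
  tab2 <- toy_table(counts[, perm], lib[perm], batches[perm, ])
  expect_equal(batch_expression(tab2, "b1", f[colnames(counts)[perm]]), b1)
  expect_error(batch_expression(tab, "nope"), "batch")
})

test_that("gene expression sums circRNAs per parent and conserves mass", {
  counts <- matrix(c(7, 3, 11, 2), 4, 1,
                   dimnames = list(c("chr1:+:1:100", "chr1:+:1:200",
                                     "chr1:+:1:300", "chr1:+:1:400"), "d1"))
  ann <- data.frame(chrom = "chr1", strand = "+", start = 1L,
                    end = c(100L, 200L, 300L, 400L),
                    parent_gene_id = c("G1", "G1", "G2", NA),
                    stringsAsFactors = FALSE)
  tab <- toy_table(counts)
  ge <- gene_expression(ann, tab)
  expect_equal(ge$genes["G1", "d1"], 10)
  expect_equal(ge$genes["G2", "d1"], 11)
  expect_equal(unname(ge$residual), 2)
  expect_equal(sum(ge$genes) + sum(ge$residual), sum(counts))

  ann_none <- transform(ann, parent_gene_id = NA_character_)
  ge2 <- gene_expression(ann_none, tab)
  expect_equal(nrow(ge2$genes), 0L)
  expect_equal(unname(ge2$residual), sum(counts))
})

test_that("Top-N ranking is deterministic with lexicographic tie-breaks", {
  set.seed(3)
  v <- stats::setNames(sample(1000, 150), sprintf("c%03d", 1:150))
  top <- top_n(v, 100)
  expect_length(top, 100)
  expect_equal(top, names(sort(v, decreasing = TRUE))[1:100])
  expect_length(top_n(v, length(v)), 150)

  ties <- stats::setNames(c(5, 5, 5, 9), c("b", "a", "c", "z"))
  expect_equal(top_n(ties, 2), c("z", "a"))
  short <- stats::setNames(c(1, 0, 0), c("a", "b", "c"))
  expect_message(got <- top_n(short, 2), "nonzero")
  expect_equal(got, "a")

  # rankings are invariant under monotone transforms
  expect_equal(top_n(sqrt(v), 100), top)
})

test_that("Top-N overlap percentage behaves like a set overlap", {
  a <- sprintf("c%03d", 1:100)
  expect_equal(overlap_pct(a, a), 100)
  expect_equal(overlap_pct(a, sprintf("x%03d", 1:100)), 0)
  b <- c(a[1:72], sprintf("y%03d", 1:28))
  expect_equal(overlap_pct(a, b), 72)
  expect_equal(overlap_pct(b, a), 72)
  expect_error(overlap_pct(a, a[1:50]), "length")
})

test_that("isoform balance reports dominance and range ratios", {
  ib <- isoform_balance(c(100, 10, 5))
  expect_equal(ib$n_isoforms, 3L)
  expect_equal(ib$dominance_ratio, 10)
  expect_equal(ib$max_min_ratio, 20)
  expect_equal(isoform_balance(7)$dominance_ratio, Inf)
})

test_that("cross-species correlation filters on log10 > 1.2 on both sides", {
  ids <- sprintf("g%03d", 1:6)
  a <- stats::setNames(c(100, 200, 400, 800, 10, 1600), ids)
  b <- 3 * a
  map <- data.frame(id_a = ids, id_b = ids, stringsAsFactors = FALSE)
  out <- cross_expression_correlation(a, b, map)
  expect_equal(out$r, 1)
  expect_equal(out$n_pairs, 5L)  # the log10 = 1 entry is excluded

  expect_error(cross_expression_correlation(a[1:3] * 0 + 1, b[1:3], map[1:3, ]),
               "fewer than 3")

  # recovers a planted correlation within sampling error (Fisher bound)
  set.seed(77)
  n <- 500; rho <- 0.7
  z <- matrix(rnorm(2 * n), ncol = 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
  ea <- stats::setNames(10^(z[, 1] * 0.5 + 2.5), sprintf("c%d", 1:n))
  eb <- stats::setNames(10^(z[, 2] * 0.5 + 2.5), sprintf("c%d", 1:n))
  mp <- data.frame(id_a = names(ea), id_b = names(eb))
  est <- cross_expression_correlation(ea, eb, mp)
  expect_lt(abs(est$r - rho), 0.08)
})

test_that("batch count comparison gives exact rank-sum p-values", {
  out <- compare_batch_counts(c(1, 2, 3), c(10, 11, 12))
  expect_equal(out$p_value, 0.1)  # 2/20, smallest attainable at 3 vs 3
  same <- compare_batch_counts(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$p_value, 1)
  sep6 <- compare_batch_counts(1:6, 101:106)
  expect_equal(sep6$p_value, 2 / choose(12, 6))
  expect_lte(sep6$p_value, 0.016)
  expect_error(compare_batch_counts(1, c(2, 3)), "at least 2")
})
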