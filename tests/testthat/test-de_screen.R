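make_expr <- function(case, control, ids = paste0("p", seq_len(nrow(case)))) {
  vals <- cbind(case, control)
  rownames(vals) <- ids
  colnames(vals) <- c(paste0("c", seq_len(ncol(case))),
                      paste0("k", seq_len(ncol(control))))
  expression_matrix(vals, rep(c("case", "control"),
                              c(ncol(case), ncol(control))))
}

test_that("log2 fold change matches the fold-change threshold arithmetic", {
  m <- make_expr(matrix(2.4, 1, 3), matrix(2.0, 1, 3))
  expect_equal(log2_fold_change(m, "p1"), log2(1.2), tolerance = 1e-12)
  # the DEP threshold 0.263 is the log2 of a 1.2-fold change
  expect_equal(2^0.263, 1.2, tolerance = 0.002)

  same <- make_expr(matrix(5, 1, 3), matrix(5, 1, 3))
  expect_equal(log2_fold_change(same, "p1"), 0)
  dbl <- make_expr(matrix(c(2, 4, 8), 1, 3), matrix(c(1, 2, 4), 1, 3))
  expect_equal(log2_fold_change(dbl, "p1"), 1)
})

test_that("strongly separated groups give a tiny p, equal groups give 1", {
  set.seed(4)
  case <- matrix(2^rnorm(10, 3.0, 0.1), 1, 10)
  ctrl <- matrix(2^rnorm(10, 1.0, 0.1), 1, 10)
  m <- make_expr(case, ctrl)
  expect_lt(de_test(m, "p1", "welch"), 1e-6)

  eq <- make_expr(matrix(2^c(1, 2, 3), 1, 3), matrix(2^c(1, 2, 3), 1, 3))
  expect_equal(de_test(eq, "p1", "welch"), 1)
})

test_that("null p-values are calibrated near the nominal level", {
  pm <- simulate_protein_matrix(protein_sim_config(
    n_proteins = 1000, n_case = 33, n_control = 31, seed = 11))
  for (method in c("welch", "moderated")) {
    de <- de_screen(pm$matrix, method = method)
    expect_gte(mean(de$pval < 0.05), 0.04)
    expect_lte(mean(de$pval < 0.05), 0.06)
  }
})

test_that("the moderated test approaches the pooled t-test as shrinkage vanishes", {
  # wildly heterogeneous per-protein variances force d0 (hence the
  # shrinkage weight d0/(d0+d)) toward zero
  set.seed(8)
  P <- 200
  sds <- exp(runif(P, -3, 3))
  vals <- 2^matrix(rnorm(P * 12, 10, sds), P, 12)
  dimnames(vals) <- list(paste0("p", 1:P), paste0("s", 1:12))
  m <- expression_matrix(vals, rep(c("case", "control"), each = 6))
  mod <- de_screen(m, "moderated")
  pooled_p <- apply(log2(m$values), 1, function(x)
    t.test(x[1:6], x[7:12], var.equal = TRUE)$p.value)
  expect_equal(mod$pval, unname(pooled_p), tolerance = 0.02)
})

test_that("the moderated test agrees with an external empirical-Bayes fit", {
  pm <- simulate_protein_matrix(protein_sim_config(
    n_proteins = 400, n_case = 10, n_control = 10,
    dep_log2fc = setNames(rep(1, 20), sprintf("prot%04d", 1:20)),
    seed = 13))
  ours <- de_screen(pm$matrix, "moderated")
  design <- cbind(1, as.numeric(pm$matrix$group == "case"))
  fit <- limma::eBayes(limma::lmFit(log2(pm$matrix$values), design))
  theirs <- fit$p.value[, 2]
  expect_gt(cor(-log10(ours$pval), -log10(theirs)), 0.99)
})

test_that("DEP classification follows the threshold rule and partitions", {
  res <- data.frame(protein_id = c("a", "b", "c", "d"),
                    log2fc = c(0.3, -0.3, 0.5, 0.1),
                    pval = c(0.01, 0.04, 0.06, 0.001))
  out <- classify_deps(res)
  expect_equal(out$de_class, c("up", "down", "ns", "ns"))
  # order invariance
  out2 <- classify_deps(res[c(3, 1, 4, 2), ])
  expect_equal(out2$de_class[out2$protein_id == "b"], "down")
  expect_setequal(out$de_class, c("up", "down", "ns"))
})

test_that("volcano table transforms and clamps p-values", {
  res <- classify_deps(data.frame(protein_id = c("a", "b"),
                                  log2fc = c(0.4, 0),
                                  pval = c(0.01, 1e-320)))
  v <- volcano_table(res)
  expect_equal(v$neg_log10_p[1], 2)
  expect_equal(v$neg_log10_p[2], 300)
  expect_true(v$p_clamped[2])
  expect_equal(v$de_class, res$de_class)
})

test_that("the screen recovers spiked DEPs on the study-sized array", {
  fc <- setNames(rep(c(1, -1), 15), sprintf("prot%04d", 1:30))
  pm <- simulate_protein_matrix(protein_sim_config(
    n_proteins = 640, n_case = 33, n_control = 31, dep_log2fc = fc,
    noise_sd = 0.5, seed = 3))
  de <- de_screen(pm$matrix)
  called <- de$protein_id[de$de_class != "ns"]
  recall <- mean(names(fc) %in% called)
  expect_gte(recall, 0.9)
  # raw-p DEP calls admit chance fold-change exceedances; the
  # FDR-adjusted call set is what controls false discoveries
  qcalled <- de$protein_id[de$qval < 0.05 & abs(de$log2fc) > 0.263]
  expect_lte(mean(!(qcalled %in% names(fc))), 0.1)
  # direction is recovered too
  up <- de$protein_id[de$de_class == "up"]
  expect_gt(mean(up %in% names(fc)[fc > 0]), 0.5)
})

test_that("pearson correlation handles exact, null, and degenerate input", {
  x <- 1:20
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(6)
  null <- pearson_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(null$r), 0.1)
  expect_protmr_error(pearson_correlation(rep(1, 5), 1:5),
                      "protmr_domain_error")
  expect_protmr_error(pearson_correlation(1:2, 2:3),
                      "protmr_domain_error")
})

test_that("median centering aligns sample medians", {
  set.seed(9)
  vals <- 2^matrix(rnorm(200, 10), 20, 10)
  vals[, 1] <- vals[, 1] * 4  # one shifted sample
  dimnames(vals) <- list(paste0("p", 1:20), paste0("s", 1:10))
  m <- expression_matrix(vals, rep(c("case", "control"), each = 5))
  centered <- median_center(m)
  meds <- apply(log2(centered$values), 2, median)
  expect_lt(diff(range(meds)), 1e-8)
})
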