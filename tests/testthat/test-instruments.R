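test_that("the F-statistic is (beta/se)^2", {
  expect_equal(f_statistic(0.2, 0.02), 100)
  expect_equal(f_statistic(0, 0.1), 0)
  f <- f_statistic(0.0316, 0.01)
  expect_equal(f, 9.9856)
  expect_lt(f, 10)
  expect_protmr_error(f_statistic(0.1, 0), "protmr_domain_error")
})

test_that("instrument filtering labels the first failing criterion", {
  s <- make_ss(beta = c(0.5, 0.03, 0.5, 0.5),
               se = c(0.05, 0.01, 0.05, 0.05),
               eaf = c(0.3, 0.3, 0.0005, 0.3),
               pval = c(1e-12, 1e-12, 1e-12, 0.5))
  rec <- filter_instruments(s, p_max = 1e-6)
  expect_equal(rec$status, c("kept", "removed_f", "removed_maf",
                             "removed_p"))
  expect_equal(rec$maf, pmin(s$associations$eaf, 1 - s$associations$eaf))
  # statuses partition the input
  expect_equal(sum(table(rec$status)), nrow(s$associations))
})

test_that("greedy LD pruning keeps the stronger variant within the window", {
  mk_rec <- function(pos2) {
    s <- make_ss(beta = c(0.4, 0.2), se = c(0.02, 0.02),
                 pos = c(1000000L, pos2), pval = c(1e-20, 1e-20))
    filter_instruments(s, p_max = 1e-6)
  }
  ld <- ld_matrix(matrix(c(1, .5, .5, 1), 2), c("rs001", "rs002"))

  rec <- ld_prune(mk_rec(1100000L), ld)        # 100 kb apart, r2 = 0.5
  expect_equal(rec$status, c("kept", "removed_ld"))

  ld_low <- ld_matrix(matrix(c(1, .1, .1, 1), 2), c("rs001", "rs002"))
  rec <- ld_prune(mk_rec(1100000L), ld_low)    # r2 = 0.1 -> both kept
  expect_equal(rec$status, c("kept", "kept"))

  rec <- ld_prune(mk_rec(1600000L), ld)        # 600 kb -> outside window
  expect_equal(rec$status, c("kept", "kept"))
})

test_that("LD pruning is order-invariant and demands complete LD data", {
  s <- make_ss(beta = c(0.4, 0.3, 0.2), se = rep(0.02, 3),
               pos = c(1e6, 1.1e6, 1.2e6), pval = rep(1e-20, 3))
  rec <- filter_instruments(s, p_max = 1e-6)
  r2 <- matrix(c(1, .5, .1, .5, 1, .1, .1, .1, 1), 3)
  ld <- ld_matrix(r2, rec$variant_id)
  pruned <- ld_prune(rec, ld)
  shuffled <- ld_prune(rec[c(3, 1, 2), ], ld)
  expect_equal(shuffled[order(shuffled$variant_id), "status"],
               pruned[order(pruned$variant_id), "status"])

  ld_partial <- ld_matrix(diag(2), c("rs001", "rs003"))
  expect_protmr_error(ld_prune(rec, ld_partial),
                      "protmr_data_completeness_error")
})

test_that("proxy lookup takes the best qualifying candidate with tie rules", {
  out <- make_ss(beta = c(0.1, 0.1, 0.1), se = rep(0.02, 3),
                 ids = c("rsA", "rsB", "rsC"),
                 pos = c(5e6, 2e6, 9e6), type = "binary")
  ids <- c("target", "rsA", "rsB", "rsC")
  mk_ld <- function(r2s) {
    m <- diag(4)
    m[1, 2:4] <- r2s; m[2:4, 1] <- r2s
    ld_matrix(m, ids)
  }
  expect_equal(find_proxy("target", out, mk_ld(c(0.95, 0.85, 0.2))), "rsA")
  expect_equal(find_proxy("target", out, mk_ld(c(0.7, 0.6, 0.2))),
               NA_character_)
  # tie at 0.9: rsB wins on smaller position
  expect_equal(find_proxy("target", out, mk_ld(c(0.9, 0.9, 0.2))), "rsB")
  expect_protmr_error(find_proxy("rsA", out, mk_ld(c(0.9, 0.9, 0.2))),
                      "protmr_misuse_error")
})

test_that("proxy substitution relabels and orients the outcome record", {
  expo <- make_ss(beta = 0.4, se = 0.02, ids = "target", eaf = 0.2,
                  pval = 1e-20)
  out <- make_ss(beta = c(0.1, 0.3), se = c(0.02, 0.02),
                 ids = c("rsP", "rsQ"), eaf = c(0.75, 0.3),
                 pos = c(2e6, 3e6), type = "binary")
  ld <- ld_matrix({m <- diag(3); m[1, 2] <- m[2, 1] <- 0.9; m},
                  c("target", "rsP", "rsQ"))
  res <- proxy_outcome(expo, out, ld)
  expect_equal(res$proxies$proxy, "rsP")
  expect_true(res$proxies$flipped)  # 1 - 0.75 is closer to 0.2
  rec <- res$outcome$associations
  prow <- rec[rec$variant_id == "target", ]
  expect_equal(prow$beta, -0.1)
  expect_equal(prow$eaf, 0.25)
})

test_that("harmonization aligns, flips, and is idempotent", {
  expo <- make_ss(beta = 0.10, se = 0.01, ids = "rs1", ea = "A", oa = "G")
  outc <- make_ss(beta = -0.05, se = 0.02, ids = "rs1", ea = "G", oa = "A",
                  eaf = 0.7, type = "binary")
  h <- harmonize(expo, outc)
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$action, "flipped")
  expect_equal(h$eaf_out, 0.3)

  # already-aligned input is unchanged (idempotence)
  outc2 <- make_ss(beta = h$beta_out, se = h$se_out, ids = "rs1",
                   ea = "A", oa = "G", eaf = h$eaf_out, type = "binary")
  h2 <- harmonize(expo, outc2)
  expect_equal(h2$beta_out, h$beta_out)
  expect_equal(h2$action, "aligned")
})

test_that("harmonization output is invariant to outcome orientation", {
  set.seed(15)
  J <- 6
  expo <- make_ss(beta = rnorm(J, 0.3, 0.05), se = rep(0.01, J),
                  eaf = runif(J, 0.1, 0.4))
  by <- rnorm(J, 0.05, 0.02)
  flip <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  outc <- make_ss(beta = ifelse(flip, -by, by), se = rep(0.02, J),
                  ea = ifelse(flip, "G", "A"), oa = ifelse(flip, "A", "G"),
                  eaf = ifelse(flip, 0.7, 0.3), type = "binary")
  h <- harmonize(expo, outc)
  expect_equal(h$beta_out, by, tolerance = 1e-12)
  expect_equal(h$eaf_out, rep(0.3, J))
})

test_that("palindromic variants follow the ambiguity policy", {
  expo <- make_ss(beta = c(0.1, 0.1, 0.1), se = rep(0.01, 3),
                  ea = c("A", "A", "A"), oa = c("T", "T", "G"),
                  eaf = c(0.2, 0.2, 0.2))
  outc <- make_ss(beta = c(0.05, 0.05, 0.05), se = rep(0.01, 3),
                  ea = c("A", "A", "A"), oa = c("T", "T", "G"),
                  eaf = c(0.50, 0.85, 0.2), type = "binary")
  h <- harmonize(expo, outc)
  # eaf 0.50 is inside the ambiguity window -> dropped
  expect_equal(h$action[1], "dropped")
  expect_equal(h$reason[1], "ambiguous_palindromic")
  # frequencies disagree (0.2 vs 0.85) -> strand flip inferred
  expect_equal(h$action[2], "flipped")
  expect_equal(h$beta_out[2], -0.05)
  # non-palindromic untouched
  expect_equal(h$action[3], "aligned")

  h_drop <- harmonize(expo, outc, palindromic_policy = "drop")
  expect_equal(h_drop$action[1:2], c("dropped", "dropped"))
  # mismatched allele sets are dropped with a reason
  outc_bad <- make_ss(beta = c(0.05, 0.05), se = c(0.01, 0.01),
                      ids = c("rs001", "rs003"), ea = c("C", "A"),
                      oa = c("T", "G"), type = "binary")
  h_bad <- harmonize(expo, outc_bad)
  expect_equal(h_bad$reason[h_bad$variant_id == "rs001"],
               "allele_mismatch")
  expect_equal(h_bad$action[h_bad$variant_id == "rs003"], "aligned")
})
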