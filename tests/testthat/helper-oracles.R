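# Shared builders and independent oracles for the test suite.

options(protmr.verbose = FALSE)

# Build a summary_stats object from effect vectors with aligned A/G
# alleles on distinct positions.
make_ss <- function(beta, se, ids = sprintf("rs%03d", seq_along(beta)),
                    eaf = 0.3, chrom = "1",
                    pos = 1000000L * seq_along(beta),
                    ea = "A", oa = "G", pval = NULL, n = 10000,
                    trait = "trait", type = "continuous") {
  df <- data.frame(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se,
    pval = pval %||% pmax(2 * pnorm(-abs(beta / se)), 1e-300),
    n = n, stringsAsFactors = FALSE)
  summary_stats(df, trait, type)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Harmonized set with every record aligned (shared alleles).
make_h <- function(bx, by, sx = 0.01, sy = 0.05, ...) {
  harmonize(make_ss(bx, rep_len(sx, length(bx)), trait = "exp", ...),
            make_ss(by, rep_len(sy, length(by)), trait = "out",
                    type = "binary", ...))
}

# Brute-force BH step-up: q_i = min over {j : p_j >= p_i} of m p_j / r_j
# with r_j the number of p-values <= p_j.
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    js <- which(p >= pi)
    min(1, min(vapply(js, function(j) m * p[j] / sum(p <= p[j]), 0)))
  }, 0)
}

# Zero-intercept weighted least squares slope via lm().
oracle_wls_slope <- function(bx, by, sy) {
  unname(coef(lm(by ~ 0 + bx, weights = 1 / sy^2)))
}

# Egger closed form via lm() after exposure-positive orientation.
oracle_egger <- function(bx, by, sy) {
  s <- sign(bx)
  fit <- lm(I(by * s) ~ I(abs(bx)), weights = 1 / sy^2)
  unname(coef(fit))
}

expect_protmr_error <- function(expr, class) {
  expect_error(expr, class = class)
}
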