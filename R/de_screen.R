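# Differential-expression screen for two-group protein arrays. Tests run
# on log2-transformed intensities; the moderated test shrinks per-protein
# variances toward a common prior by empirical Bayes.

split_groups <- function(m) {
  list(case = m$values[, m$group == "case", drop = FALSE],
       control = m$values[, m$group == "control", drop = FALSE])
}

#' Log2 fold change for one protein
#'
#' Computed as the difference of group means of log2 intensities
#' (case minus control), i.e. the log2 ratio of geometric means. The
#' arithmetic-mean-ratio alternative (`log2(mean(case)/mean(control))`) is
#' available via `method`.
#'
#' @param m An [expression_matrix()].
#' @param protein_id Protein to evaluate.
#' @param method `"log_means"` (default) or `"mean_ratio"`.
#' @return Log2 fold change (scalar).
#' @export
log2_fold_change <- function(m, protein_id,
                             method = c("log_means", "mean_ratio")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "expression_matrix"))
  if (!protein_id %in% rownames(m$values)) {
    pm_stop(paste0("unknown protein: ", protein_id), "protmr_domain_error")
  }
  g <- split_groups(m)
  x <- g$case[protein_id, ]; y <- g$control[protein_id, ]
  if (method == "mean_ratio") return(log2(mean(x) / mean(y)))
  if (any(x <= 0) || any(y <= 0)) {
    pm_stop("nonpositive intensity cannot be log-transformed",
            "protmr_range_error")
  }
  mean(log2(x)) - mean(log2(y))
}

# Vectorized two-group stats on the log2 scale.
group_moments <- function(m) {
  if (any(m$values <= 0)) {
    pm_stop("nonpositive intensity cannot be log-transformed",
            "protmr_range_error")
  }
  lv <- log2(m$values)
  case <- lv[, m$group == "case", drop = FALSE]
  ctrl <- lv[, m$group == "control", drop = FALSE]
  list(n1 = ncol(case), n2 = ncol(ctrl),
       m1 = rowMeans(case), m2 = rowMeans(ctrl),
       v1 = apply(case, 1L, var), v2 = apply(ctrl, 1L, var))
}

# Inverse of trigamma by Newton iteration (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    step <- (tri - y) / psigamma(x, 2L)
    x <- x - step
    if (x <= 0) x <- .Machine$double.eps
    if (abs(step) < 1e-10 * x) break
  }
  x
}

# Empirical-Bayes variance moderation: pooled per-protein variances are
# shrunk toward a common prior s0^2 with weight d0/(d0 + d); (d0, s0^2) are
# fit by method of moments on log sample variances.
moderate_variances <- function(s2, d) {
  s2 <- pmax(s2, 1e-12)
  e <- log(s2)
  evar <- var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s0_2 <- exp(mean(e) - digamma(d / 2) + log(d / 2))
    post <- rep(s0_2, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) - digamma(d / 2) + log(d / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = post)
}

de_test_all <- function(m, method = c("moderated", "welch")) {
  method <- match.arg(method)
  gm <- group_moments(m)
  diff <- gm$m1 - gm$m2
  if (method == "welch") {
    vsum <- gm$v1 / gm$n1 + gm$v2 / gm$n2
    tstat <- diff / sqrt(vsum)
    df <- vsum^2 / ((gm$v1 / gm$n1)^2 / (gm$n1 - 1) +
                      (gm$v2 / gm$n2)^2 / (gm$n2 - 1))
    p <- 2 * pt(-abs(tstat), df)
  } else {
    d <- gm$n1 + gm$n2 - 2
    s2 <- ((gm$n1 - 1) * gm$v1 + (gm$n2 - 1) * gm$v2) / d
    mod <- moderate_variances(s2, d)
    tstat <- diff / sqrt(mod$s2_post * (1 / gm$n1 + 1 / gm$n2))
    df <- d + mod$d0
    p <- if (is.finite(mod$d0)) 2 * pt(-abs(tstat), df) else
      two_sided_p(tstat)
  }
  degenerate <- !is.finite(p)
  if (any(degenerate)) {
    # zero variance in both groups: p = 1 when the means agree too
    p[degenerate] <- ifelse(abs(diff[degenerate]) < 1e-12, 1, 1e-300)
    pm_log(sum(degenerate), " protein(s) with degenerate variance; ",
           "p set by mean comparison")
  }
  data.frame(protein_id = rownames(m$values), log2fc = unname(diff),
             pval = pmin(unname(p), 1), stringsAsFactors = FALSE)
}

#' Two-group test for one protein
#'
#' Two-sided p-value comparing group means of log2 intensities. `"welch"`
#' is the unequal-variance t-test; `"moderated"` shrinks the pooled
#' per-protein variance toward the across-protein prior via an
#' empirical-Bayes weight `d0/(d0 + d)` and tests on `d + d0` degrees of
#' freedom (moderation is fit on the full matrix).
#'
#' @param m An [expression_matrix()].
#' @param protein_id Protein to test.
#' @param method `"welch"` or `"moderated"`.
#' @return Two-sided p-value.
#' @export
de_test <- function(m, protein_id, method = c("welch", "moderated")) {
  method <- match.arg(method)
  res <- de_test_all(m, method)
  if (!protein_id %in% res$protein_id) {
    pm_stop(paste0("unknown protein: ", protein_id), "protmr_domain_error")
  }
  res$pval[res$protein_id == protein_id]
}

#' Classify differentially expressed proteins
#'
#' A protein is `up` when `log2fc > fc_threshold` and `pval < p_threshold`,
#' `down` when `log2fc < -fc_threshold` and `pval < p_threshold`, `ns`
#' otherwise. The default thresholds (|log2FC| > 0.263, p < 0.05)
#' correspond to a linear fold change above 1.2 or below 0.83.
#' Benjamini-Hochberg q-values are reported alongside but, per the DEP
#' rule, classification uses the raw p-value.
#'
#' @param results data.frame with `protein_id`, `log2fc`, `pval`.
#' @param fc_threshold,p_threshold Positive thresholds.
#' @return `results` with added `qval` and `de_class` columns.
#' @export
classify_deps <- function(results, fc_threshold = 0.263,
                          p_threshold = 0.05) {
  assert_scalar_number(fc_threshold, "fc_threshold", 0, open_lower = TRUE)
  assert_scalar_number(p_threshold, "p_threshold", 0, 1, open_lower = TRUE)
  stopifnot(all(c("protein_id", "log2fc", "pval") %in% names(results)))
  results$qval <- bh_fdr(results$pval)
  sig <- results$pval < p_threshold
  results$de_class <- ifelse(sig & results$log2fc > fc_threshold, "up",
                             ifelse(sig & results$log2fc < -fc_threshold,
                                    "down", "ns"))
  results
}

#' Volcano-plot table
#'
#' One row per protein with `log2fc`, `-log10(p)` and the DE class, ready
#' for any plotting layer. P-values below `p_floor` are clamped and
#' flagged.
#'
#' @param results Output of [classify_deps()].
#' @param p_floor Smallest representable p-value.
#' @return data.frame with `protein_id`, `log2fc`, `neg_log10_p`,
#'   `de_class`, `p_clamped`.
#' @export
volcano_table <- function(results, p_floor = 1e-300) {
  if (nrow(results) == 0L) {
    pm_stop("no DE results to tabulate", "protmr_empty_input_error")
  }
  clamped <- results$pval < p_floor
  data.frame(protein_id = results$protein_id, log2fc = results$log2fc,
             neg_log10_p = -log10(pmax(results$pval, p_floor)),
             de_class = results$de_class, p_clamped = clamped,
             stringsAsFactors = FALSE)
}

#' Run the full differential-expression screen
#'
#' Log2 fold changes and per-protein tests for every protein, classified by
#' [classify_deps()].
#'
#' @param m An [expression_matrix()].
#' @param method Test passed to [de_test()].
#' @param fc_threshold,p_threshold Thresholds for [classify_deps()].
#' @param normalize Apply per-sample median centering first (off by
#'   default: array inputs are assumed vendor-normalized upstream).
#' @return data.frame with `protein_id`, `log2fc`, `pval`, `qval`,
#'   `de_class`.
#' @export
de_screen <- function(m, method = c("moderated", "welch"),
                      fc_threshold = 0.263, p_threshold = 0.05,
                      normalize = FALSE) {
  method <- match.arg(method)
  if (normalize) m <- median_center(m)
  classify_deps(de_test_all(m, method), fc_threshold, p_threshold)
}

#' Per-sample median centering
#'
#' Centers each sample's log2 intensities on the grand median. A light
#' inter-sample normalization utility for inputs that did not go through
#' vendor normalization; off by default throughout the package.
#'
#' @param m An [expression_matrix()].
#' @return A normalized [expression_matrix()].
#' @export
median_center <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  lv <- log2(pmax(m$values, .Machine$double.xmin))
  med <- apply(lv, 2L, median)
  lv <- sweep(lv, 2L, med - median(med))
  expression_matrix(2^lv, m$group)
}

#' Pearson correlation with a two-sided test
#'
#' Sample correlation between two numeric vectors with the two-sided
#' p-value from the t transform (wraps [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and `pval`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    pm_stop("x and y must have equal length >= 3", "protmr_domain_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    pm_stop("correlation undefined for zero-variance input",
            "protmr_domain_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pval = ct$p.value)
}
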