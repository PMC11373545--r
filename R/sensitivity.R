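# Sensitivity suite: leave-one-out, MR-PRESSO (global / outlier /
# distortion), funnel-plot data and the Egger-intercept pleiotropy test.

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect with each instrument removed in turn, plus
#' the all-instrument row, to expose single-variant leverage.
#'
#' @param h A `harmonized_set` with >= 3 retained variants.
#' @param model IVW model (see [mr_ivw()]).
#' @return data.frame with `J + 1` rows: `excluded` (variant id or
#'   `"(none)"`), `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
leave_one_out <- function(h, model = "auto") {
  v <- h_vectors(h, 3L, "leave_one_out")
  k <- h_kept(h)
  rows <- lapply(seq_len(v$J), function(j) {
    sub <- h[h$variant_id != v$id[j] | h$action == "dropped", ,
             drop = FALSE]
    est <- mr_ivw(sub, model)
    cbind(excluded = v$id[j], as.data.frame(est)[
      c("n_snp", "beta", "se", "ci_low", "ci_high", "pval")])
  })
  all_est <- mr_ivw(h, model)
  rows <- c(rows, list(cbind(excluded = "(none)", as.data.frame(all_est)[
    c("n_snp", "beta", "se", "ci_low", "ci_high", "pval")])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Leave-one-out IVW slopes for every variant at once.
# bx, by: J x n matrices (or vectors); so: length-J outcome SEs.
loo_slopes <- function(bx, by, so) {
  bx <- as.matrix(bx); by <- as.matrix(by)
  w <- 1 / so^2
  s1 <- colSums(bx^2 * w)
  s2 <- colSums(bx * by * w)
  num <- matrix(s2, nrow(bx), ncol(bx), byrow = TRUE) - bx * by * w
  den <- matrix(s1, nrow(bx), ncol(bx), byrow = TRUE) - bx^2 * w
  num / den
}

#' MR-PRESSO residual-sum-and-outlier test
#'
#' Detects and corrects instruments with pleiotropic effects by comparing
#' each variant's outcome estimate with the value expected from the IVW
#' slope fitted on the other instruments. The observed weighted residual
#' sum of squares is referred to a parametric simulation under the
#' no-pleiotropy model (`beta_exp* ~ N(beta_exp, se_exp^2)`,
#' `beta_out* ~ N(expected, se_out^2)`), giving a global test; per-variant
#' residuals referred to their simulated distributions give
#' Bonferroni-adjusted outlier p-values; a corrected IVW estimate is
#' computed on the non-outliers; and an optional distortion test compares
#' the corrected-vs-original shift against random removals of the same
#' number of variants. Empirical p-values use the `(1 + k)/(n + 1)`
#' correction.
#'
#' @param h A `harmonized_set` with >= 4 retained variants.
#' @param n_sim Simulation replicates.
#' @param seed Seed for the simulations.
#' @param outlier_alpha Threshold on the Bonferroni-adjusted outlier p.
#' @param distortion Run the distortion test when outliers are found.
#' @return List of class `presso_result`: `rss_obs`, `global_p`,
#'   `outlier_p` (named, adjusted), `outlier_ids`, `corrected` (an
#'   [mr_estimate()] or `NULL`), `distortion_p` (or `NA`), `n_sim`,
#'   `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000L, seed = 1L, outlier_alpha = 0.05,
                      distortion = TRUE) {
  v <- h_vectors(h, 4L, "mr_presso")
  J <- v$J
  w <- 1 / v$sy^2
  theta_loo <- drop(loo_slopes(v$bx, v$by, v$sy))
  expected <- theta_loo * v$bx
  r_obs <- w * (v$by - expected)^2
  rss_obs <- sum(r_obs)

  sims <- withr::with_seed(seed, {
    bx_s <- matrix(rnorm(J * n_sim, v$bx, v$sx), J, n_sim)
    by_s <- matrix(rnorm(J * n_sim, expected, v$sy), J, n_sim)
    loo_s <- loo_slopes(bx_s, by_s, v$sy)
    r_s <- (by_s - loo_s * bx_s)^2 * w
    list(r = r_s, rss = colSums(r_s))
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  outlier_p_raw <- (1 + rowSums(sims$r >= r_obs)) / (n_sim + 1)
  outlier_p <- setNames(pmin(1, outlier_p_raw * J), v$id)
  outlier_ids <- v$id[outlier_p < outlier_alpha]

  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outlier_ids) > 0 && J - length(outlier_ids) >= 2L) {
    sub <- h[!(h$variant_id %in% outlier_ids) | h$action == "dropped", ,
             drop = FALSE]
    corr_ivw <- mr_ivw(sub, "auto")
    corrected <- mr_estimate("presso_corrected", corr_ivw$n_snp,
                             corr_ivw$beta, corr_ivw$se,
                             extra = corr_ivw$extra)
    if (distortion) {
      beta_all <- mr_ivw(h, "auto")$beta
      d_obs <- corrected$beta - beta_all
      n_out <- length(outlier_ids)
      d_sim <- withr::with_seed(split_seed(seed, 7L), {
        vapply(seq_len(n_sim), function(b) {
          drop_idx <- sample.int(J, n_out)
          wk <- w[-drop_idx]; bxk <- v$bx[-drop_idx]; byk <- v$by[-drop_idx]
          sum(wk * bxk * byk) / sum(wk * bxk^2) - beta_all
        }, 0)
      })
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
    }
  }
  structure(list(rss_obs = rss_obs, global_p = global_p,
                 outlier_p = outlier_p, outlier_ids = outlier_ids,
                 corrected = corrected, distortion_p = distortion_p,
                 n_sim = as.integer(n_sim), seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS %.4g, global p %.3g (%d sims)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outlier_ids)) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "),
        sprintf("; corrected beta %.4f; distortion p %.3g\n",
                x$corrected$beta, x$distortion_p))
  } else cat("  no outliers detected\n")
  invisible(x)
}

#' Funnel-plot data
#'
#' Per-variant Wald ratio against its precision (`1/se`); asymmetry about
#' the pooled estimate suggests directional pleiotropy.
#'
#' @param h A `harmonized_set`.
#' @return data.frame with `variant_id`, `theta`, `precision`.
#' @export
funnel_data <- function(h) {
  v <- h_vectors(h, 1L, "funnel_data")
  data.frame(variant_id = v$id, theta = v$by / v$bx,
             precision = abs(v$bx) / v$sy, stringsAsFactors = FALSE)
}

#' Egger-intercept horizontal-pleiotropy test
#'
#' Re-exports the [mr_egger()] intercept (value, SE, two-sided t p-value)
#' as the directional-pleiotropy report.
#'
#' @param h A `harmonized_set` with >= 3 retained variants.
#' @return List with `value`, `se`, `pval`, `df`.
#' @export
pleiotropy_report <- function(h) {
  mr_egger(h)$intercept
}
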