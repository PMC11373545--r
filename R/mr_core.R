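# Two-sample MR estimator suite: Wald ratio, fixed/random-effects IVW,
# MR-Egger, weighted median, weighted mode, Cochran's Q and BH correction.

#' Construct an MR estimate
#'
#' Normalizes one method's causal estimate into the common reporting shape:
#' 95% CI on the log-odds scale, odds ratio with exponentiated bounds, and
#' a two-sided p-value (normal by default, t when `df` is given).
#'
#' @param method Method tag.
#' @param n_snp Number of instruments used.
#' @param beta,se Causal estimate (log-odds per exposure SD) and SE.
#' @param df Degrees of freedom for a t-based p-value; `NULL` for normal.
#' @param extra Method-specific named list (e.g. Egger intercept).
#' @return Object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, n_snp, beta, se, df = NULL,
                        extra = list()) {
  z <- qnorm(0.975)
  pval <- if (is.null(df)) two_sided_p(beta / se) else
    2 * pt(-abs(beta / se), df)
  structure(list(method = method, n_snp = as.integer(n_snp),
                 beta = beta, se = se,
                 ci_low = beta - z * se, ci_high = beta + z * se,
                 or = exp(beta), or_low = exp(beta - z * se),
                 or_high = exp(beta + z * se),
                 pval = max(min(pval, 1), .Machine$double.xmin),
                 extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta %.4f (SE %.4f), OR %.3f [%.3f, %.3f], p %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$or, x$or_low, x$or_high,
              x$pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, or = x$or,
             or_low = x$or_low, or_high = x$or_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

h_vectors <- function(h, min_snp = 1L, caller = "estimator") {
  k <- h_kept(h)
  if (nrow(k) < min_snp) {
    pm_stop(sprintf("%s requires at least %d instruments (%d available)",
                    caller, min_snp, nrow(k)),
            "protmr_insufficient_instruments_error")
  }
  if (any(k$beta_exp == 0)) {
    pm_stop("degenerate instrument with zero exposure effect",
            "protmr_degenerate_instrument_error")
  }
  list(bx = k$beta_exp, sx = k$se_exp, by = k$beta_out, sy = k$se_out,
       id = k$variant_id, J = nrow(k))
}

#' Wald ratio estimate from a single instrument
#'
#' `beta_out / beta_exp`, with first-order delta SE `se_out / |beta_exp|`
#' (the common default); `second_order = TRUE` adds the exposure-noise
#' term.
#'
#' @param h A `harmonized_set` with exactly one retained variant.
#' @param second_order Include the exposure SE in the delta expansion.
#' @return An [mr_estimate()].
#' @export
wald_ratio <- function(h, second_order = FALSE) {
  v <- h_vectors(h, 1L, "wald_ratio")
  if (v$J != 1L) {
    pm_stop("wald_ratio expects exactly one instrument",
            "protmr_misuse_error")
  }
  beta <- v$by / v$bx
  se <- if (second_order) {
    sqrt(v$sy^2 / v$bx^2 + v$by^2 * v$sx^2 / v$bx^4)
  } else {
    v$sy / abs(v$bx)
  }
  mr_estimate("wald", 1L, beta, se)
}

ivw_weights <- function(v) v$bx^2 / v$sy^2

#' Inverse-variance-weighted MR estimate
#'
#' Precision-weighted mean of per-variant Wald ratios with weights
#' `beta_exp^2 / se_out^2` (equivalently the zero-intercept weighted
#' least-squares slope of `beta_out` on `beta_exp`). The fixed-effect SE is
#' `(sum w)^(-1/2)`; the random-effects model inflates it by
#' `max(1, sqrt(Q/(J-1)))`; `model = "auto"` (the default) switches to
#' random effects when Cochran's Q has p <= 0.05. A single instrument
#' delegates to [wald_ratio()].
#'
#' @param h A `harmonized_set`.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return An [mr_estimate()]; `extra` carries `model_used`, `q`, `q_pval`.
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  v <- h_vectors(h, 1L, "mr_ivw")
  if (v$J == 1L) return(wald_ratio(h))
  w <- ivw_weights(v)
  theta <- v$by / v$bx
  beta <- sum(w * theta) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  q <- sum(w * (theta - beta)^2)
  q_pval <- pchisq(q, v$J - 1L, lower.tail = FALSE)
  used <- switch(model,
                 fixed = "fixed",
                 random = "random",
                 auto = if (q_pval <= 0.05) "random" else "fixed")
  se <- if (used == "random") se_fe * max(1, sqrt(q / (v$J - 1L))) else se_fe
  tag <- if (used == "random") "ivw_re" else "ivw_fe"
  mr_estimate(tag, v$J, beta, se,
              extra = list(model_used = used, q = q, q_pval = q_pval))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - beta)^2` around the supplied estimate, with
#' `J - 1` degrees of freedom (`J - 2` for an Egger estimate, where the
#' residuals are taken about the fitted line). `I^2 = max(0, (Q - df)/Q)`.
#'
#' @param h A `harmonized_set`.
#' @param at An [mr_estimate()] the residuals are taken about.
#' @return List of class `heterogeneity_result`: `q`, `df`, `pval`, `i2`.
#' @export
cochran_q <- function(h, at) {
  stopifnot(inherits(at, "mr_estimate"))
  v <- h_vectors(h, 2L, "cochran_q")
  w <- 1 / v$sy^2
  if (identical(at$method, "egger")) {
    df <- v$J - 2L
    int <- at$extra$intercept
    q <- sum(w * (sign(v$bx) * v$by - int - at$beta * abs(v$bx))^2)
  } else {
    df <- v$J - 1L
    wq <- ivw_weights(v)
    q <- sum(wq * (v$by / v$bx - at$beta)^2)
  }
  structure(list(q = q, df = df,
                 pval = pchisq(q, df, lower.tail = FALSE),
                 i2 = if (q > 0) max(0, (q - df) / q) else 0),
            class = "heterogeneity_result")
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome effects on the
#' exposure effects with an intercept, after orienting every variant so
#' the exposure effect is nonnegative; weights `se_out^(-2)`. Standard
#' errors are inflated by `max(1, sqrt(Q_egger/(J-2)))` and p-values use
#' `t(J-2)`. The intercept is the directional-pleiotropy test. With
#' `intercept = FALSE` the regression is forced through the origin and the
#' slope reproduces the fixed-effect IVW estimate.
#'
#' @param h A `harmonized_set` with >= 3 retained variants.
#' @param intercept Fit the pleiotropy intercept (default) or constrain it
#'   to zero.
#' @return List with `slope` (an [mr_estimate()], `extra` carrying the
#'   intercept record and `q`) and `intercept` (list of `value`, `se`,
#'   `pval`, `df`).
#' @export
mr_egger <- function(h, intercept = TRUE) {
  v <- h_vectors(h, 3L, "mr_egger")
  s <- sign(v$bx)
  bx <- abs(v$bx)
  by <- v$by * s
  if (sd(bx) == 0) {
    pm_stop("no spread in |beta_exp|; Egger regression is collinear",
            "protmr_collinearity_error")
  }
  w <- 1 / v$sy^2
  X <- if (intercept) cbind(1, bx) else cbind(bx)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * by)
  coefs <- unname(drop(solve(XtWX, XtWy)))
  fitted <- drop(X %*% coefs)
  df <- v$J - ncol(X)
  q <- sum(w * (by - fitted)^2)
  scale <- max(1, sqrt(q / df))
  ses <- sqrt(diag(solve(XtWX))) * scale
  if (!intercept) {
    slope <- mr_estimate("egger_noint", v$J, coefs[1L], ses[1L], df = df,
                         extra = list(q = q))
    return(list(slope = slope, intercept = NULL))
  }
  int <- list(value = coefs[1L], se = ses[1L],
              pval = 2 * pt(-abs(coefs[1L] / ses[1L]), df), df = df)
  slope <- mr_estimate("egger", v$J, coefs[2L], ses[2L], df = df,
                       extra = list(intercept = int$value,
                                    intercept_se = int$se,
                                    intercept_pval = int$pval, q = q))
  list(slope = slope, intercept = int)
}

ratio_stats <- function(v) {
  theta <- v$by / v$bx
  se_theta <- v$sy / abs(v$bx)
  w <- 1 / se_theta^2
  list(theta = theta, w = w / sum(w))
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(theta[1L])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  stats::approx(p, theta, xout = 0.5, ties = "ordered")$y
}

mode_bandwidth <- function(theta, bandwidth_factor) {
  J <- length(theta)
  bandwidth_factor * 0.9 * min(sd(theta), IQR(theta) / 1.34) * J^(-1 / 5)
}

weighted_mode_point <- function(theta, w, bandwidth_factor = 1,
                                grid_n = 512L) {
  bw <- mode_bandwidth(theta, bandwidth_factor)
  if (!is.finite(bw) || bw <= 0) return(theta[which.max(w)])
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw, length.out = grid_n)
  dens <- drop(dnorm(outer(grid, theta, "-"), sd = bw) %*% w)
  grid[which.max(dens)]
}

# Parametric bootstrap SE shared by weighted median and mode: perturb
# (beta_exp, beta_out) by their SEs and recompute the point estimate.
bootstrap_se <- function(v, point_fun, n_boot, seed) {
  est <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(v$J, v$bx, v$sx)
      by <- rnorm(v$J, v$by, v$sy)
      bx[bx == 0] <- .Machine$double.eps
      theta <- by / bx
      se_theta <- v$sy / abs(bx)
      w <- 1 / se_theta^2
      point_fun(theta, w / sum(w))
    }, 0)
  })
  sd(est)
}

#' Weighted-median MR estimate
#'
#' Median of the inverse-variance-weighted empirical distribution of the
#' per-variant Wald ratios (cumulative midpoint weights, linear
#' interpolation at probability 1/2); consistent when at least half of the
#' total instrument weight is valid. The SE is a seeded parametric
#' bootstrap over the summary statistics.
#'
#' @param h A `harmonized_set` with >= 3 retained variants.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return An [mr_estimate()].
#' @export
weighted_median <- function(h, n_boot = 1000L, seed = 1L) {
  v <- h_vectors(h, 3L, "weighted_median")
  rs <- ratio_stats(v)
  beta <- weighted_median_point(rs$theta, rs$w)
  se <- bootstrap_se(v, weighted_median_point, n_boot, seed)
  mr_estimate("weighted_median", v$J, beta, se,
              extra = list(n_boot = n_boot, seed = seed))
}

# Vectorized parametric bootstrap for the weighted mode: all replicates'
# ratio sets, bandwidths and density grids are evaluated as whole
# matrices (R recycles length-B vectors down the columns of the
# B x grid matrices). Replicate modes use a coarser grid than the point
# estimate: 128 points resolve an SE comfortably.
bootstrap_se_mode <- function(v, bandwidth_factor, n_boot, seed,
                              grid_n = 128L) {
  est <- withr::with_seed(seed, {
    BX <- matrix(rnorm(v$J * n_boot, v$bx, v$sx), v$J, n_boot)
    BX[BX == 0] <- .Machine$double.eps
    BY <- matrix(rnorm(v$J * n_boot, v$by, v$sy), v$J, n_boot)
    TH <- BY / BX
    W <- BX^2 / v$sy^2
    W <- sweep(W, 2L, colSums(W), "/")
    sds <- apply(TH, 2L, sd)
    iqrs <- apply(TH, 2L, IQR)
    bw <- bandwidth_factor * 0.9 * pmin(sds, iqrs / 1.34) * v$J^(-1 / 5)
    ok <- is.finite(bw) & bw > 0
    est <- numeric(n_boot)
    if (any(!ok)) {
      est[!ok] <- TH[cbind(apply(W[, !ok, drop = FALSE], 2L, which.max),
                           which(!ok))]
    }
    if (any(ok)) {
      B <- sum(ok)
      THo <- TH[, ok, drop = FALSE]; Wo <- W[, ok, drop = FALSE]
      bwo <- bw[ok]
      lo <- apply(THo, 2L, min) - 3 * bwo
      hi <- apply(THo, 2L, max) + 3 * bwo
      G <- lo + outer(hi - lo, seq(0, 1, length.out = grid_n))
      D <- matrix(0, B, grid_n)
      for (j in seq_len(v$J)) {
        D <- D + Wo[j, ] * dnorm((G - THo[j, ]) / bwo) / bwo
      }
      idx <- max.col(D, ties.method = "first")
      est[ok] <- G[cbind(seq_len(B), idx)]
    }
    est
  })
  sd(est)
}

#' Weighted-mode MR estimate
#'
#' Argmax of a weighted normal-kernel density of the Wald ratios
#' (bandwidth `bandwidth_factor * 0.9 * min(sd, IQR/1.34) * J^(-1/5)`, 512
#' grid points spanning the ratios plus/minus 3 bandwidths); consistent
#' when the largest group of instruments sharing a causal estimate is
#' valid. Bootstrap SE as in [weighted_median()]. If all ratios coincide
#' the common ratio is returned and logged.
#'
#' @param h A `harmonized_set` with >= 3 retained variants.
#' @param bandwidth_factor Multiplier on the default bandwidth.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return An [mr_estimate()].
#' @export
weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000L,
                          seed = 1L) {
  v <- h_vectors(h, 3L, "weighted_mode")
  rs <- ratio_stats(v)
  if (mode_bandwidth(rs$theta, bandwidth_factor) <= 0) {
    pm_log("all Wald ratios identical; weighted mode returns the common ",
           "ratio")
  }
  beta <- weighted_mode_point(rs$theta, rs$w, bandwidth_factor)
  se <- bootstrap_se_mode(v, bandwidth_factor, n_boot, seed)
  mr_estimate("weighted_mode", v$J, beta, se,
              extra = list(bandwidth_factor = bandwidth_factor,
                           n_boot = n_boot, seed = seed))
}

#' Run every applicable MR estimator
#'
#' Wald ratio when a single instrument is available; IVW for two or more;
#' MR-Egger, weighted median and weighted mode from three instruments up.
#' Bootstrap seeds are split deterministically from `seed`.
#'
#' @param h A `harmonized_set`.
#' @param seed Root seed for the bootstrap-based estimators.
#' @param n_boot Bootstrap replicates.
#' @param model IVW model (see [mr_ivw()]).
#' @param bandwidth_factor Passed to [weighted_mode()].
#' @return List with `estimates` (data.frame, one row per method) and
#'   `heterogeneity` (data.frame of Cochran's Q about the IVW and Egger
#'   fits, `NULL` when fewer than 2 instruments).
#' @export
estimate_all <- function(h, seed = 1L, n_boot = 1000L,
                         model = c("auto", "fixed", "random"),
                         bandwidth_factor = 1) {
  model <- match.arg(model)
  v <- h_vectors(h, 1L, "estimate_all")
  ests <- list()
  het <- NULL
  if (v$J == 1L) {
    ests$wald <- wald_ratio(h)
  } else {
    ivw <- mr_ivw(h, model)
    ests$ivw <- ivw
    qi <- cochran_q(h, ivw)
    het <- data.frame(method = "ivw", q = qi$q, df = qi$df,
                      pval = qi$pval, i2 = qi$i2, stringsAsFactors = FALSE)
    if (v$J >= 3L) {
      eg <- mr_egger(h)
      ests$egger <- eg$slope
      ests$weighted_median <- weighted_median(
        h, n_boot, seed = split_seed(seed, 1L))
      ests$weighted_mode <- weighted_mode(
        h, bandwidth_factor, n_boot, seed = split_seed(seed, 2L))
      qe <- cochran_q(h, eg$slope)
      het <- rbind(het, data.frame(method = "egger", q = qe$q, df = qe$df,
                                   pval = qe$pval, i2 = qe$i2,
                                   stringsAsFactors = FALSE))
    }
  }
  estimates <- do.call(rbind, lapply(ests, as.data.frame))
  rownames(estimates) <- NULL
  list(estimates = estimates, heterogeneity = het, objects = ests)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values via [stats::p.adjust()] with
#' `method = "BH"`; inputs must lie in (0, 1].
#'
#' @param pvals Numeric vector of p-values.
#' @return q-values of the same length (empty input gives empty output).
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    pm_stop("p-values must lie in (0, 1]", "protmr_domain_error")
  }
  p.adjust(pvals, method = "BH")
}
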