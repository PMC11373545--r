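# Network MR: two-step screening of candidate mediators and the
# product-of-coefficients decomposition with proportion mediated.

leg_ivw <- function(h, model = "auto") {
  est <- mr_ivw(h, model)
  list(beta = est$beta, se = est$se, pval = est$pval, n_snp = est$n_snp)
}

#' Two-step screen of candidate mediators
#'
#' Estimates both legs per mediator by IVW (auto model): the
#' exposure-to-mediator leg and the mediator-to-outcome leg. A mediator is
#' screened in when both leg p-values fall below `alpha`; mediators with a
#' missing leg are skipped with a log entry.
#'
#' @param em_sets Named list of `harmonized_set`s, exposure instruments
#'   against each mediator.
#' @param mo_sets Named list of `harmonized_set`s, each mediator's
#'   instruments against the outcome.
#' @param alpha Screening significance level for both legs.
#' @return data.frame with one row per mediator: leg estimates, SEs,
#'   p-values, instrument counts and `screened_in`.
#' @export
two_step_screen <- function(em_sets, mo_sets, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", 0, 1, open_lower = TRUE)
  mediators <- union(names(em_sets), names(mo_sets))
  rows <- lapply(mediators, function(med) {
    if (is.null(em_sets[[med]]) || is.null(mo_sets[[med]])) {
      pm_log("mediator ", med, " skipped: missing leg")
      return(NULL)
    }
    em <- leg_ivw(em_sets[[med]])
    mo <- leg_ivw(mo_sets[[med]])
    data.frame(mediator = med,
               n_snp_em = em$n_snp, beta_em = em$beta, se_em = em$se,
               pval_em = em$pval,
               n_snp_mo = mo$n_snp, beta_mo = mo$beta, se_mo = mo$se,
               pval_mo = mo$pval,
               screened_in = em$pval < alpha && mo$pval < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    pm_stop("no mediator had both legs available",
            "protmr_empty_input_error")
  }
  rownames(out) <- NULL
  out
}

#' Product-of-coefficients mediation decomposition
#'
#' Indirect effect `beta_em * beta_mo` with delta-method SE
#' `sqrt(beta_em^2 se_mo^2 + beta_mo^2 se_em^2)`; direct effect
#' `beta_total - indirect`; proportion mediated `indirect / beta_total`
#' with a first-order delta SE treating the legs and the total effect as
#' independent (non-overlapping samples). All inputs on the linear (log)
#' scale: pass `log(OR)` for binary traits.
#'
#' @param beta_em,se_em Exposure-to-mediator effect and SE.
#' @param beta_mo,se_mo Mediator-to-outcome effect (log-odds) and SE.
#' @param beta_total,se_total Total exposure-to-outcome effect (log-odds)
#'   and SE; must be nonzero.
#' @param mediator Optional mediator label.
#' @return List of class `mediation_result`: `indirect`, `se_indirect`,
#'   `direct`, `pm`, `pm_se`, `pm_ci_low`, `pm_ci_high` plus the inputs.
#' @export
decompose_mediation <- function(beta_em, se_em, beta_mo, se_mo,
                                beta_total, se_total,
                                mediator = NA_character_) {
  for (nm in c("beta_em", "se_em", "beta_mo", "se_mo", "beta_total",
               "se_total")) {
    assert_scalar_number(get(nm), nm)
  }
  if (beta_total == 0) {
    pm_stop("proportion mediated undefined for a zero total effect",
            "protmr_undefined_pm_error")
  }
  z <- qnorm(0.975)
  indirect <- beta_em * beta_mo
  se_indirect <- sqrt(beta_em^2 * se_mo^2 + beta_mo^2 * se_em^2)
  pm <- indirect / beta_total
  pm_se <- sqrt(se_indirect^2 / beta_total^2 +
                  indirect^2 * se_total^2 / beta_total^4)
  structure(list(mediator = mediator,
                 beta_em = beta_em, se_em = se_em,
                 beta_mo = beta_mo, se_mo = se_mo,
                 beta_total = beta_total, se_total = se_total,
                 indirect = indirect, se_indirect = se_indirect,
                 direct = beta_total - indirect,
                 pm = pm, pm_se = pm_se,
                 pm_ci_low = pm - z * pm_se, pm_ci_high = pm + z * pm_se),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation%s: indirect %.4f (SE %.4f), PM %.1f%% (SE %.1f%%)\n",
              if (is.na(x$mediator)) "" else paste0(" via ", x$mediator),
              x$indirect, x$se_indirect, 100 * x$pm, 100 * x$pm_se))
  invisible(x)
}

#' Mediation report table
#'
#' Combines the two-step screen with per-mediator decompositions into one
#' report: leg estimates with odds ratios and CIs, and the proportion
#' mediated formatted as a percentage with one decimal for screened-in
#' mediators, `"-"` otherwise.
#'
#' @param screen Output of [two_step_screen()].
#' @param decompositions Named list of [decompose_mediation()] results for
#'   the screened-in mediators.
#' @return data.frame, one row per mediator.
#' @export
mediation_table <- function(screen, decompositions = list()) {
  if (nrow(screen) == 0L) {
    pm_stop("no mediators to report", "protmr_empty_input_error")
  }
  z <- qnorm(0.975)
  pm_cell <- vapply(seq_len(nrow(screen)), function(i) {
    med <- screen$mediator[i]
    d <- decompositions[[med]]
    if (isTRUE(screen$screened_in[i]) && !is.null(d)) {
      sprintf("%.1f%%", 100 * d$pm)
    } else "-"
  }, "")
  data.frame(
    mediator = screen$mediator,
    n_snp_em = screen$n_snp_em,
    beta_em = screen$beta_em, se_em = screen$se_em,
    pval_em = screen$pval_em,
    n_snp_mo = screen$n_snp_mo,
    or_mo = exp(screen$beta_mo),
    or_mo_low = exp(screen$beta_mo - z * screen$se_mo),
    or_mo_high = exp(screen$beta_mo + z * screen$se_mo),
    pval_mo = screen$pval_mo,
    screened_in = screen$screened_in,
    pm = pm_cell,
    stringsAsFactors = FALSE)
}
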