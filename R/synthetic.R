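# Synthetic-data generators. Every downstream stage is testable against
# known ground truth: simulated pQTL/GWAS summary statistics under a
# configurable causal effect with optional pleiotropy, mediation trios with
# known proportion mediated, and a protein-array matrix with spiked group
# differences.

NONPALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                                 "G", "A", "G", "T", "T", "C", "T", "G"),
                               ncol = 2L, byrow = TRUE)

#' Configuration for a simulated two-sample MR dataset
#'
#' Encodes the structural model behind two-sample MR: true instrument
#' effects `gamma_j ~ N(0, gamma_sd^2)` truncated away from zero
#' (`|gamma_j| >= 0.5 * gamma_sd`), observed exposure effects
#' `beta_x ~ N(gamma, se_x^2)`, a pleiotropic path `alpha_j` that is zero
#' with probability `1 - prop_invalid` and `N(pleio_mean, pleio_sd^2)`
#' otherwise, and observed outcome effects
#' `beta_y ~ N(theta * gamma + alpha, se_y^2)`.
#'
#' @param n_snp Number of instruments (>= 1).
#' @param theta True causal effect (log-odds per exposure SD).
#' @param gamma_sd SD of true instrument effects (exposure SD units).
#' @param se_x,se_y Per-variant standard errors (scalar or length `n_snp`).
#' @param prop_invalid Fraction of instruments with a pleiotropic path.
#' @param pleio_mean,pleio_sd Directional-pleiotropy distribution.
#' @param orient_gamma Code every effect allele as exposure-increasing
#'   (`gamma_j = |gamma_j|`). Directional pleiotropy is then directional
#'   relative to the exposure-raising orientation, the setting in which
#'   the Egger intercept identifies its mean.
#' @param eaf_range Range effect-allele frequencies are drawn from.
#' @param n_exp,n_out GWAS sample sizes written into the outputs.
#' @param exposure_name,outcome_name Trait labels.
#' @param outcome_type `"binary"` (betas are log-odds) or `"continuous"`.
#' @param id_prefix Variant-id prefix (keeps ids unique across datasets).
#' @param seed Root seed; every draw is reproducible given it.
#' @return A validated config list of class `mr_sim_config`.
#' @export
mr_sim_config <- function(n_snp = 5L, theta = 0, gamma_sd = 0.3,
                          se_x = 0.02, se_y = 0.03, prop_invalid = 0,
                          pleio_mean = 0, pleio_sd = 0.1,
                          orient_gamma = FALSE,
                          eaf_range = c(0.05, 0.5),
                          n_exp = 5343L, n_out = 184305L,
                          exposure_name = "exposure",
                          outcome_name = "outcome",
                          outcome_type = c("binary", "continuous"),
                          id_prefix = "rs_sim", seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  assert_scalar_number(n_snp, "n_snp", lower = 1)
  assert_scalar_number(theta, "theta")
  assert_scalar_number(gamma_sd, "gamma_sd", lower = 0, open_lower = TRUE)
  if (any(se_x <= 0) || any(se_y <= 0)) {
    pm_stop("se_x and se_y must be positive", "protmr_domain_error")
  }
  if (!(length(se_x) %in% c(1L, n_snp)) || !(length(se_y) %in% c(1L, n_snp))) {
    pm_stop("se_x/se_y must be scalar or length n_snp", "protmr_domain_error")
  }
  assert_scalar_number(prop_invalid, "prop_invalid", lower = 0, upper = 1)
  assert_scalar_number(pleio_sd, "pleio_sd", lower = 0)
  structure(list(n_snp = as.integer(n_snp), theta = theta,
                 gamma_sd = gamma_sd, se_x = se_x, se_y = se_y,
                 prop_invalid = prop_invalid, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, orient_gamma = isTRUE(orient_gamma),
                 eaf_range = eaf_range,
                 n_exp = n_exp, n_out = n_out,
                 exposure_name = exposure_name,
                 outcome_name = outcome_name,
                 outcome_type = outcome_type,
                 id_prefix = id_prefix, seed = seed),
            class = "mr_sim_config")
}

# Normal draws truncated to |x| >= lower.
rnorm_trunc_away <- function(n, sd, lower) {
  x <- rnorm(n, 0, sd)
  while (any(bad <- abs(x) < lower)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
  }
  x
}

#' Simulate a two-sample MR summary-statistics dataset
#'
#' Generates exposure and outcome [summary_stats()] sharing variant ids
#' (non-palindromic alleles, EAF uniform on `cfg$eaf_range`, spaced 1 Mb
#' apart across chromosomes so no simulated pair falls in an LD window),
#' plus the ground-truth record.
#'
#' @param cfg An [mr_sim_config()].
#' @return List with `exposure`, `outcome` ([summary_stats()]), `truth`
#'   (data.frame of `variant_id`, `gamma`, `alpha`, `invalid`) and `theta`.
#' @export
simulate_mr_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  withr::with_seed(cfg$seed, {
    J <- cfg$n_snp
    gamma <- rnorm_trunc_away(J, cfg$gamma_sd, 0.5 * cfg$gamma_sd)
    if (cfg$orient_gamma) gamma <- abs(gamma)
    invalid <- runif(J) < cfg$prop_invalid
    alpha <- ifelse(invalid, rnorm(J, cfg$pleio_mean, cfg$pleio_sd), 0)
    se_x <- rep_len(cfg$se_x, J)
    se_y <- rep_len(cfg$se_y, J)
    beta_x <- rnorm(J, gamma, se_x)
    beta_y <- rnorm(J, cfg$theta * gamma + alpha, se_y)
    eaf <- runif(J, cfg$eaf_range[1], cfg$eaf_range[2])
    pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), J,
                                            replace = TRUE), , drop = FALSE]
    ids <- sprintf("%s%04d", cfg$id_prefix, seq_len(J))
    base <- data.frame(
      variant_id = ids,
      chrom = as.character(((seq_len(J) - 1L) %% 22L) + 1L),
      pos = 1000000L * (((seq_len(J) - 1L) %/% 22L) + 1L),
      effect_allele = pair[, 1L], other_allele = pair[, 2L],
      eaf = eaf, stringsAsFactors = FALSE)
    exp_df <- base
    exp_df$beta <- beta_x; exp_df$se <- se_x
    exp_df$pval <- pmax(two_sided_p(beta_x / se_x), 1e-300)
    exp_df$n <- cfg$n_exp
    out_df <- base
    out_df$beta <- beta_y; out_df$se <- se_y
    out_df$pval <- pmax(two_sided_p(beta_y / se_y), 1e-300)
    out_df$n <- cfg$n_out
    list(exposure = summary_stats(exp_df, cfg$exposure_name, "continuous"),
         outcome = summary_stats(out_df, cfg$outcome_name, cfg$outcome_type),
         truth = data.frame(variant_id = ids, gamma = gamma, alpha = alpha,
                            invalid = invalid, stringsAsFactors = FALSE),
         theta = cfg$theta)
  })
}

#' Configuration for a simulated mediation trio
#'
#' A trio of independent two-sample MR datasets for exposure-to-mediator,
#' mediator-to-outcome and exposure-to-outcome legs, generated under the
#' linear structural model in which the exposure-to-outcome total effect is
#' `theta_dir + theta_em * theta_mo`, so the true proportion mediated is
#' `theta_em * theta_mo / (theta_dir + theta_em * theta_mo)`.
#'
#' @param theta_em Exposure-to-mediator effect.
#' @param theta_mo Mediator-to-outcome effect (log-odds per mediator SD).
#' @param theta_dir Direct exposure-to-outcome effect.
#' @param n_snp Instruments per leg (scalar or length 3: em, mo, eo).
#' @param gamma_sd,se_x,se_y As in [mr_sim_config()], shared across legs.
#' @param seed Root seed; per-leg seeds are split deterministically.
#' @return A config list of class `mediation_sim_config`.
#' @export
mediation_sim_config <- function(theta_em = 0.1, theta_mo = 0.5,
                                 theta_dir = 0.05, n_snp = 5L,
                                 gamma_sd = 0.3, se_x = 0.02, se_y = 0.03,
                                 seed = 1L) {
  total <- theta_dir + theta_em * theta_mo
  if (abs(total) < .Machine$double.eps^0.5) {
    pm_stop("total effect theta_dir + theta_em * theta_mo must be nonzero",
            "protmr_config_error")
  }
  structure(list(theta_em = theta_em, theta_mo = theta_mo,
                 theta_dir = theta_dir, theta_total = total,
                 n_snp = rep_len(as.integer(n_snp), 3L),
                 gamma_sd = gamma_sd, se_x = se_x, se_y = se_y, seed = seed),
            class = "mediation_sim_config")
}

#' Simulate a mediation trio of MR datasets
#'
#' @param cfg A [mediation_sim_config()].
#' @return List with elements `em`, `mo`, `eo` (each the output of
#'   [simulate_mr_dataset()]) and `truth` (list with the leg effects,
#'   `theta_total` and `pm`, the true proportion mediated).
#' @export
simulate_mediation_trio <- function(cfg) {
  stopifnot(inherits(cfg, "mediation_sim_config"))
  legs <- list(
    em = list(theta = cfg$theta_em, n = cfg$n_snp[1], stream = 1L,
              exp = "exposure", out = "mediator", type = "continuous"),
    mo = list(theta = cfg$theta_mo, n = cfg$n_snp[2], stream = 2L,
              exp = "mediator", out = "outcome", type = "binary"),
    eo = list(theta = cfg$theta_total, n = cfg$n_snp[3], stream = 3L,
              exp = "exposure", out = "outcome", type = "binary"))
  out <- lapply(names(legs), function(nm) {
    lg <- legs[[nm]]
    simulate_mr_dataset(mr_sim_config(
      n_snp = lg$n, theta = lg$theta, gamma_sd = cfg$gamma_sd,
      se_x = cfg$se_x, se_y = cfg$se_y,
      exposure_name = lg$exp, outcome_name = lg$out,
      outcome_type = lg$type, id_prefix = paste0("rs_", nm),
      seed = split_seed(cfg$seed, lg$stream)))
  })
  names(out) <- names(legs)
  out$truth <- list(theta_em = cfg$theta_em, theta_mo = cfg$theta_mo,
                    theta_dir = cfg$theta_dir,
                    theta_total = cfg$theta_total,
                    pm = cfg$theta_em * cfg$theta_mo / cfg$theta_total)
  out
}

#' Configuration for a simulated protein-array matrix
#'
#' Emulates a two-group serum protein-array experiment on the log2 scale:
#' per-protein baselines uniform on `baseline_range`, within-group noise
#' `N(0, noise_sd^2)`, and case-group means shifted by the assigned log2
#' fold change for the spiked proteins. Defaults mirror a 640-protein array
#' measured in 33 cases and 31 controls.
#'
#' @param n_proteins,n_case,n_control Dimensions (groups >= 2 samples).
#' @param dep_log2fc Named numeric vector: names are spiked protein ids
#'   (must exist), values their true log2 fold changes. `NULL` for none.
#' @param noise_sd Within-group SD on the log2 scale.
#' @param baseline_range Range of per-protein baseline log2 intensities.
#' @param seed Root seed.
#' @return A config list of class `protein_sim_config`.
#' @export
protein_sim_config <- function(n_proteins = 640L, n_case = 33L,
                               n_control = 31L, dep_log2fc = NULL,
                               noise_sd = 0.5, baseline_range = c(8, 14),
                               seed = 1L) {
  assert_scalar_number(n_case, "n_case", lower = 2)
  assert_scalar_number(n_control, "n_control", lower = 2)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  ids <- sprintf("prot%04d", seq_len(n_proteins))
  if (!is.null(dep_log2fc)) {
    if (is.null(names(dep_log2fc)) || !all(names(dep_log2fc) %in% ids)) {
      pm_stop("dep_log2fc must be named by existing protein ids",
              "protmr_config_error")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 protein_ids = ids, dep_log2fc = dep_log2fc,
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 seed = seed),
            class = "protein_sim_config")
}

#' Simulate a protein-array expression matrix with spiked DEPs
#'
#' @param cfg A [protein_sim_config()].
#' @return List with `matrix` (an [expression_matrix()], linear-scale
#'   intensities) and `truth` (data.frame of `protein_id`, `true_log2fc`).
#' @export
simulate_protein_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "protein_sim_config"))
  withr::with_seed(cfg$seed, {
    P <- cfg$n_proteins
    n <- cfg$n_case + cfg$n_control
    baseline <- runif(P, cfg$baseline_range[1], cfg$baseline_range[2])
    true_fc <- setNames(numeric(P), cfg$protein_ids)
    if (!is.null(cfg$dep_log2fc)) {
      true_fc[names(cfg$dep_log2fc)] <- cfg$dep_log2fc
    }
    log2v <- matrix(rnorm(P * n, mean = baseline, sd = cfg$noise_sd),
                    nrow = P, ncol = n)
    log2v[, seq_len(cfg$n_case)] <- log2v[, seq_len(cfg$n_case)] + true_fc
    rownames(log2v) <- cfg$protein_ids
    colnames(log2v) <- c(sprintf("case%02d", seq_len(cfg$n_case)),
                         sprintf("ctrl%02d", seq_len(cfg$n_control)))
    group <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
    list(matrix = expression_matrix(2^log2v, group),
         truth = data.frame(protein_id = cfg$protein_ids,
                            true_log2fc = unname(true_fc),
                            stringsAsFactors = FALSE))
  })
}

#' Write a complete synthetic study bundle for the pipeline
#'
#' Generates the full set of files [run_pipeline()] consumes: a spiked
#' protein-array matrix with groups, one pQTL summary-statistics file per
#' spiked protein, a shared disease-outcome summary-statistics file, an LD
#' matrix over all instruments (identity: simulated instruments are
#' unlinked), truth tables and a ready-to-run YAML config. Exactly one
#' spiked protein (the first) carries a causal effect `theta_causal` on the
#' outcome; the other spiked proteins are differentially expressed but
#' causally null.
#'
#' @param dir Output directory (created if needed).
#' @param n_proteins,n_case,n_control,noise_sd As [protein_sim_config()].
#' @param n_dep Number of spiked proteins.
#' @param dep_log2fc Magnitude of the spiked log2 fold changes (signs
#'   alternate).
#' @param theta_causal Causal log-odds effect of the causal protein.
#' @param n_snp Instruments simulated per spiked protein.
#' @param gamma_sd,se_x,se_y Structural-model parameters per
#'   [mr_sim_config()].
#' @param seed Root seed.
#' @return List with `dir`, `config` (path to the YAML), and `truth`
#'   (causal protein id, spiked ids, per-protein theta).
#' @export
simulate_study_bundle <- function(dir, n_proteins = 640L, n_case = 33L,
                                  n_control = 31L, noise_sd = 0.5,
                                  n_dep = 30L, dep_log2fc = 1,
                                  theta_causal = 0.3, n_snp = 5L,
                                  gamma_sd = 0.3, se_x = 0.01, se_y = 0.03,
                                  seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exp_dir <- file.path(dir, "exposures")
  dir.create(exp_dir, showWarnings = FALSE)

  ids <- sprintf("prot%04d", seq_len(n_proteins))
  dep_ids <- withr::with_seed(split_seed(seed, 101L),
                              sample(ids, n_dep))
  fc <- setNames(dep_log2fc * rep_len(c(1, -1), n_dep), dep_ids)
  causal_protein <- dep_ids[1L]

  pm <- simulate_protein_matrix(protein_sim_config(
    n_proteins = n_proteins, n_case = n_case, n_control = n_control,
    dep_log2fc = fc, noise_sd = noise_sd,
    seed = split_seed(seed, 102L)))
  write_expression(pm$matrix, file.path(dir, "expression.tsv"),
                   file.path(dir, "groups.tsv"))

  theta_by_protein <- setNames(rep(0, n_dep), dep_ids)
  theta_by_protein[causal_protein] <- theta_causal
  out_rows <- vector("list", n_dep)
  for (i in seq_len(n_dep)) {
    pid <- dep_ids[i]
    sim <- simulate_mr_dataset(mr_sim_config(
      n_snp = n_snp, theta = theta_by_protein[pid], gamma_sd = gamma_sd,
      se_x = se_x, se_y = se_y, exposure_name = pid,
      outcome_name = "disease", id_prefix = paste0(pid, "_v"),
      seed = split_seed(seed, 200L + i)))
    write_sumstats(sim$exposure, file.path(exp_dir, paste0(pid, ".tsv")))
    out_rows[[i]] <- sim$outcome$associations
  }
  outcome <- summary_stats(do.call(rbind, out_rows), "disease", "binary")
  write_sumstats(outcome, file.path(dir, "outcome.tsv"))

  all_ids <- outcome$associations$variant_id
  ld <- ld_matrix(diag(length(all_ids)), all_ids)
  write_ld_matrix(ld, file.path(dir, "ld.tsv"))

  truth <- data.frame(protein_id = dep_ids,
                      true_log2fc = unname(fc[dep_ids]),
                      theta = unname(theta_by_protein[dep_ids]),
                      stringsAsFactors = FALSE)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cfg <- list(
    expression = list(matrix = "expression.tsv", groups = "groups.tsv"),
    exposures = list(dir = "exposures"),
    outcome = list(path = "outcome.tsv", name = "disease"),
    ld = list(path = "ld.tsv"),
    seed = as.integer(seed %% 2147483647),
    output_dir = "results")
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)

  list(dir = dir, config = cfg_path,
       truth = list(causal_protein = causal_protein, dep_ids = dep_ids,
                    dep_log2fc = fc, theta = theta_by_protein,
                    truth_table = truth))
}
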