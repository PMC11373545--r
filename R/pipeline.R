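# Configuration-driven orchestration of the full study design:
# DE screen -> instrument selection per DEP -> harmonization -> MR
# estimator suite -> FDR across proteins -> sensitivity suite ->
# mediation -> power, with TSV reports and a run manifest.

pipeline_defaults <- function() {
  list(
    expression = list(matrix = NULL, groups = NULL),
    exposures = list(dir = NULL),
    outcome = list(path = NULL, name = "outcome", type = "binary"),
    ld = list(path = NULL),
    mediators = list(),
    de = list(method = "moderated", fc_threshold = 0.263,
              p_threshold = 0.05, normalize = FALSE),
    instruments = list(p_max = 0.05 / 54469 / 4782, f_min = 10,
                       maf_min = 0.001, r2_max = 0.2, window_bp = 500000,
                       r2_proxy_min = 0.8, palindromic_policy = "infer"),
    mr = list(fdr_alpha = 0.05, n_boot = 1000, model = "auto"),
    mediation = list(alpha = 0.05, mediator_p_max = 5e-8),
    presso = list(n_sim = 1000, outlier_alpha = 0.05),
    power = NULL,
    sensitivity_all = FALSE,
    seed = 1,
    output_dir = "results")
}

check_known_keys <- function(cfg, defaults, prefix = "") {
  for (key in names(cfg)) {
    if (!key %in% names(defaults)) {
      pm_stop(paste0("unknown config key: ", prefix, key),
              "protmr_config_error")
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "mediators" && is.list(cfg[[key]])) {
      check_known_keys(cfg[[key]], defaults[[key]],
                       paste0(prefix, key, "."))
    }
  }
}

check_range <- function(value, key, lower, upper,
                        open_lower = FALSE, open_upper = FALSE) {
  ok_lo <- if (open_lower) value > lower else value >= lower
  ok_hi <- if (open_upper) value < upper else value <= upper
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      !ok_lo || !ok_hi) {
    pm_stop(paste0("config value out of range: ", key, " = ", value),
            "protmr_config_error")
  }
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, applies defaults, rejects unknown keys and
#' out-of-range thresholds, and resolves relative paths against the
#' config file's directory. See the package vignette for the full key
#' reference.
#'
#' @param path Path to a YAML config file, or a named list with the same
#'   structure.
#' @return A validated config list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  if (is.character(path)) {
    base_dir <- dirname(normalizePath(path, mustWork = TRUE))
    cfg <- yaml::read_yaml(path)
    cfg_file <- normalizePath(path)
  } else if (is.list(path)) {
    base_dir <- getwd()
    cfg <- path
    cfg_file <- NA_character_
  } else {
    pm_stop("config must be a file path or a named list",
            "protmr_config_error")
  }
  defaults <- pipeline_defaults()
  check_known_keys(cfg, defaults)
  merged <- modifyList(defaults, cfg)
  # modifyList drops unnamed elements: carry the mediator list over as-is
  merged$mediators <- cfg$mediators %||% list()

  for (field in c("matrix", "groups")) {
    if (is.null(merged$expression[[field]])) {
      pm_stop(paste0("missing config field: expression.", field),
              "protmr_config_error")
    }
  }
  if (is.null(merged$exposures$dir)) {
    pm_stop("missing config field: exposures.dir", "protmr_config_error")
  }
  if (is.null(merged$outcome$path)) {
    pm_stop("missing config field: outcome.path", "protmr_config_error")
  }
  check_range(merged$de$fc_threshold, "de.fc_threshold", 0, Inf,
              open_lower = TRUE)
  check_range(merged$de$p_threshold, "de.p_threshold", 0, 1,
              open_lower = TRUE)
  check_range(merged$instruments$p_max, "instruments.p_max", 0, 1,
              open_lower = TRUE)
  check_range(merged$instruments$f_min, "instruments.f_min", 0, Inf)
  check_range(merged$instruments$maf_min, "instruments.maf_min", 0, 0.5)
  check_range(merged$instruments$r2_max, "instruments.r2_max", 0, 1)
  check_range(merged$instruments$window_bp, "instruments.window_bp", 0, Inf)
  check_range(merged$instruments$r2_proxy_min, "instruments.r2_proxy_min",
              0, 1)
  check_range(merged$mr$fdr_alpha, "mr.fdr_alpha", 0, 1, open_lower = TRUE)
  check_range(merged$mr$n_boot, "mr.n_boot", 1, Inf)
  check_range(merged$mediation$alpha, "mediation.alpha", 0, 1,
              open_lower = TRUE)
  check_range(merged$presso$n_sim, "presso.n_sim", 1, Inf)
  if (!is.null(merged$power)) {
    check_range(merged$power$n_total, "power.n_total", 1, Inf)
    check_range(merged$power$case_fraction, "power.case_fraction", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
    check_range(merged$power$rsq_xz, "power.rsq_xz", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
    check_range(merged$power$alpha %||% 0.05, "power.alpha", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
  }

  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(p)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  merged$expression$matrix <- resolve(merged$expression$matrix)
  merged$expression$groups <- resolve(merged$expression$groups)
  merged$exposures$dir <- resolve(merged$exposures$dir)
  merged$outcome$path <- resolve(merged$outcome$path)
  merged$ld$path <- resolve(merged$ld$path)
  merged$mediators <- lapply(merged$mediators, function(m) {
    if (is.null(m$name) || is.null(m$path)) {
      pm_stop("each mediator needs 'name' and 'path'",
              "protmr_config_error")
    }
    m$path <- resolve(m$path)
    m
  })
  merged$output_dir <- resolve(merged$output_dir)
  for (p in c(merged$expression$matrix, merged$expression$groups,
              merged$exposures$dir, merged$outcome$path,
              if (!is.null(merged$ld$path)) merged$ld$path,
              vapply(merged$mediators, `[[`, "", "path"))) {
    if (!file.exists(p)) {
      pm_stop(paste0("config references a missing file: ", p),
              "protmr_config_error")
    }
  }
  structure(merged, class = "pipeline_config", config_file = cfg_file)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "protmr_stage_error")) stop(e)
    pm_stop(paste0("[stage ", stage, "] ", conditionMessage(e)),
            "protmr_stage_error")
  })
}

# Rebuild a summary_stats object from the kept rows of an instrument
# record table.
records_to_sumstats <- function(records, trait_name, trait_type) {
  kept <- records[records$status == "kept", ASSOC_COLUMNS, drop = FALSE]
  summary_stats(kept, trait_name, trait_type, validate = FALSE)
}

# Instrument selection for one trait: filter, prune (when LD given),
# proxy substitution against the outcome.
select_instruments <- function(s, outcome, ld, icfg, p_max = NULL) {
  rec <- filter_instruments(s, p_max = p_max %||% icfg$p_max,
                            f_min = icfg$f_min, maf_min = icfg$maf_min)
  if (!is.null(ld) && any(rec$status == "kept")) {
    rec <- ld_prune(rec, ld, icfg$r2_max, icfg$window_bp)
  }
  if (!any(rec$status == "kept")) return(list(records = rec, h = NULL))
  expo <- records_to_sumstats(rec, s$trait_name, s$trait_type)
  out_use <- outcome
  if (!is.null(ld)) {
    pr <- proxy_outcome(expo, outcome, ld, icfg$r2_proxy_min)
    out_use <- pr$outcome
    rec$status[rec$variant_id %in% pr$proxies$target] <- "proxied"
    rec$proxy_for[match(pr$proxies$target, rec$variant_id)] <-
      pr$proxies$proxy
  }
  absent <- setdiff(expo$associations$variant_id,
                    out_use$associations$variant_id)
  rec$status[rec$variant_id %in% absent] <- "removed_missing_outcome"
  h <- tryCatch(
    harmonize(expo, out_use, icfg$palindromic_policy),
    protmr_empty_harmonization_error = function(e) NULL)
  list(records = rec, h = h)
}

#' Run the full proteomics-to-causal-inference pipeline
#'
#' Executes the study design end to end: differential-expression screen,
#' per-DEP instrument selection and harmonization against the outcome, the
#' MR estimator suite per protein, Benjamini-Hochberg correction across
#' the proteins actually tested, the sensitivity suite for FDR-significant
#' proteins, network-MR mediation for the configured mediator traits, and
#' an analytic power report. All stage outputs are written as TSV files
#' into `output_dir` together with a run manifest; identical config and
#' seeds give byte-identical outputs.
#'
#' @param config A [load_config()] result, a config file path, or a named
#'   list.
#' @return Invisibly, a list with the per-stage results (`de`, `mr_all`,
#'   `heterogeneity`, `primary`, `sensitivity`, `mediation`, `power`,
#'   `manifest`, `output_dir`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- load_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # -- stage: differential expression ---------------------------------
  de <- run_stage("de_screen", {
    m <- read_expression(config$expression$matrix, config$expression$groups)
    de <- de_screen(m, method = config$de$method,
                    fc_threshold = config$de$fc_threshold,
                    p_threshold = config$de$p_threshold,
                    normalize = config$de$normalize)
    write_tsv(de, file.path(out_dir, "de_results.tsv"))
    write_tsv(volcano_table(de), file.path(out_dir, "volcano.tsv"))
    de
  })
  deps <- de$protein_id[de$de_class != "ns"]
  pm_log(length(deps), " DEP(s): ", sum(de$de_class == "up"), " up, ",
         sum(de$de_class == "down"), " down")

  # -- stage: instruments + MR per DEP --------------------------------
  outcome <- run_stage("read_outcome", read_sumstats(
    config$outcome$path, trait_name = config$outcome$name,
    trait_type = config$outcome$type))
  ld <- if (!is.null(config$ld$path)) {
    run_stage("read_ld", read_ld_matrix(config$ld$path))
  } else NULL

  skipped <- character(0)
  inst_reports <- list()
  mr_rows <- list()
  het_rows <- list()
  primary_rows <- list()
  hsets <- list()
  exposure_stats <- list()
  for (i in seq_along(deps)) {
    pid <- deps[i]
    path <- file.path(config$exposures$dir, paste0(pid, ".tsv"))
    if (!file.exists(path)) {
      skipped <- c(skipped, pid)
      next
    }
    run_stage(paste0("mr:", pid), {
      expo <- read_sumstats(path, trait_name = pid)
      sel <- select_instruments(expo, outcome, ld, config$instruments)
      inst_reports[[pid]] <- cbind(protein_id = pid, sel$records)
      if (is.null(sel$h)) {
        skipped <- c(skipped, pid)
      } else {
        hsets[[pid]] <- sel$h
        exposure_stats[[pid]] <- records_to_sumstats(
          sel$records, pid, expo$trait_type)
        res <- estimate_all(sel$h, seed = split_seed(seed, 1000 + i),
                            n_boot = config$mr$n_boot,
                            model = config$mr$model)
        mr_rows[[pid]] <- cbind(protein_id = pid, res$estimates)
        if (!is.null(res$heterogeneity)) {
          het_rows[[pid]] <- cbind(protein_id = pid, res$heterogeneity)
        }
        prim <- res$estimates[res$estimates$method %in%
                                c("wald", "ivw_fe", "ivw_re"), ,
                              drop = FALSE]
        primary_rows[[pid]] <- cbind(protein_id = pid, prim)
      }
    })
  }
  if (length(skipped)) {
    pm_log(length(skipped), " DEP(s) without usable instruments skipped: ",
           paste(skipped, collapse = ", "))
  }
  inst_report <- do.call(rbind, inst_reports)
  if (!is.null(inst_report)) {
    write_tsv(inst_report, file.path(out_dir, "instruments.tsv"))
  }
  mr_all <- do.call(rbind, mr_rows)
  het_all <- do.call(rbind, het_rows)
  primary <- do.call(rbind, primary_rows)

  significant <- character(0)
  if (!is.null(primary)) {
    rownames(primary) <- NULL
    primary$qval <- bh_fdr(primary$pval)
    primary$significant <- primary$qval < config$mr$fdr_alpha
    significant <- primary$protein_id[primary$significant]
    write_tsv(mr_all, file.path(out_dir, "mr_results.tsv"))
    if (!is.null(het_all)) {
      write_tsv(het_all, file.path(out_dir, "heterogeneity.tsv"))
    }
    write_tsv(primary, file.path(out_dir, "mr_primary.tsv"))
  } else {
    pm_log("no protein could be tested by MR; MR section empty")
  }

  # -- stage: sensitivity suite ---------------------------------------
  sens_targets <- if (isTRUE(config$sensitivity_all)) names(hsets) else
    significant
  sensitivity <- list()
  for (pid in sens_targets) {
    run_stage(paste0("sensitivity:", pid), {
      h <- hsets[[pid]]
      J <- nrow(h_kept(h))
      s <- list(funnel = funnel_data(h))
      if (J >= 3L) {
        s$leave_one_out <- leave_one_out(h, config$mr$model)
        s$pleiotropy <- pleiotropy_report(h)
      }
      if (J >= 4L) {
        s$presso <- mr_presso(h, n_sim = config$presso$n_sim,
                              seed = split_seed(seed, 3000 + match(
                                pid, sens_targets)),
                              outlier_alpha = config$presso$outlier_alpha)
      }
      sensitivity[[pid]] <- s
    })
  }
  if (length(sensitivity)) {
    fun <- do.call(rbind, lapply(names(sensitivity), function(p)
      cbind(protein_id = p, sensitivity[[p]]$funnel)))
    write_tsv(fun, file.path(out_dir, "funnel.tsv"))
    loo <- do.call(rbind, lapply(names(sensitivity), function(p)
      if (!is.null(sensitivity[[p]]$leave_one_out))
        cbind(protein_id = p, sensitivity[[p]]$leave_one_out)))
    if (!is.null(loo)) write_tsv(loo, file.path(out_dir, "leave_one_out.tsv"))
    pl <- do.call(rbind, lapply(names(sensitivity), function(p) {
      x <- sensitivity[[p]]$pleiotropy
      if (!is.null(x)) data.frame(protein_id = p, intercept = x$value,
                                  se = x$se, pval = x$pval)
    }))
    if (!is.null(pl)) write_tsv(pl, file.path(out_dir, "pleiotropy.tsv"))
    pr <- do.call(rbind, lapply(names(sensitivity), function(p) {
      x <- sensitivity[[p]]$presso
      if (!is.null(x)) data.frame(
        protein_id = p, rss_obs = x$rss_obs, global_p = x$global_p,
        n_outliers = length(x$outlier_ids),
        outlier_ids = paste(x$outlier_ids, collapse = ","),
        corrected_beta = if (is.null(x$corrected)) NA else x$corrected$beta,
        distortion_p = x$distortion_p, n_sim = x$n_sim)
    }))
    if (!is.null(pr)) write_tsv(pr, file.path(out_dir, "presso.tsv"))
  }

  # -- stage: mediation ------------------------------------------------
  mediation_out <- NULL
  if (length(config$mediators) && length(significant)) {
    mediation_out <- run_stage("mediation", {
      tabs <- list()
      for (pid in significant) {
        em_sets <- list(); mo_sets <- list()
        for (med in config$mediators) {
          med_stats <- read_sumstats(med$path, trait_name = med$name)
          em <- tryCatch(
            harmonize(exposure_stats[[pid]], med_stats,
                      config$instruments$palindromic_policy),
            protmr_error = function(e) NULL)
          mo <- tryCatch({
            sel <- select_instruments(
              med_stats, outcome, ld, config$instruments,
              p_max = med$p_max %||% config$mediation$mediator_p_max)
            sel$h
          }, protmr_error = function(e) NULL)
          if (!is.null(em)) em_sets[[med$name]] <- em
          if (!is.null(mo)) mo_sets[[med$name]] <- mo
        }
        screen <- two_step_screen(em_sets, mo_sets,
                                  alpha = config$mediation$alpha)
        total <- primary[primary$protein_id == pid, ][1L, ]
        dec <- list()
        for (k in which(screen$screened_in)) {
          dec[[screen$mediator[k]]] <- decompose_mediation(
            screen$beta_em[k], screen$se_em[k],
            screen$beta_mo[k], screen$se_mo[k],
            total$beta, total$se, mediator = screen$mediator[k])
        }
        tabs[[pid]] <- cbind(protein_id = pid,
                             mediation_table(screen, dec))
      }
      med_tab <- do.call(rbind, tabs)
      write_tsv(med_tab, file.path(out_dir, "mediation.tsv"))
      med_tab
    })
  }

  # -- stage: power ----------------------------------------------------
  power_out <- NULL
  if (!is.null(config$power) && length(significant)) {
    power_out <- run_stage("power", {
      rows <- lapply(significant, function(pid) {
        est <- primary[primary$protein_id == pid, ][1L, ]
        pw <- config$power
        data.frame(protein_id = pid, or = exp(est$beta),
                   n_total = pw$n_total,
                   case_fraction = pw$case_fraction,
                   rsq_xz = pw$rsq_xz, alpha = pw$alpha %||% 0.05,
                   power = mr_power_binary(pw$n_total, pw$case_fraction,
                                           exp(est$beta), pw$rsq_xz,
                                           pw$alpha %||% 0.05))
      })
      tab <- do.call(rbind, rows)
      write_tsv(tab, file.path(out_dir, "power.tsv"))
      tab
    })
  }

  # -- manifest --------------------------------------------------------
  cfg_file <- attr(config, "config_file")
  manifest <- data.frame(
    key = c("protmr_version", "config_md5", "seed", "n_proteins",
            "n_samples", "n_dep_up", "n_dep_down", "n_dep",
            "n_dep_skipped", "n_tested", "n_significant",
            "significant_proteins"),
    value = c(as.character(utils::packageVersion("protmr")),
              if (is.na(cfg_file)) "NA" else
                unname(tools::md5sum(cfg_file)),
              as.character(seed),
              as.character(nrow(de)),
              as.character(length(read_tsv_commented(
                config$expression$groups)$sample_id)),
              as.character(sum(de$de_class == "up")),
              as.character(sum(de$de_class == "down")),
              as.character(length(deps)),
              as.character(length(unique(skipped))),
              as.character(length(hsets)),
              as.character(length(significant)),
              paste(significant, collapse = ",")),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(de = de, mr_all = mr_all, heterogeneity = het_all,
                 primary = primary, sensitivity = sensitivity,
                 mediation = mediation_out, power = power_out,
                 manifest = manifest, skipped = unique(skipped),
                 harmonized = hsets, output_dir = out_dir))
}
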