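# Instrument selection and exposure/outcome harmonization.

#' Instrument strength F-statistic
#'
#' Single-variant approximation `(beta/se)^2` of the first-stage F.
#'
#' @param beta,se Association estimate and its standard error (vectors
#'   allowed; `se` must be positive).
#' @return `(beta/se)^2`.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0) || any(!is.finite(se))) {
    pm_stop("se must be positive", "protmr_domain_error")
  }
  (beta / se)^2
}

#' Select genetic instruments from pQTL summary statistics
#'
#' Applies the exposure significance, instrument-strength and allele
#' frequency filters. Each variant is labelled with the first failing
#' criterion, in the order p-value, then F-statistic, then MAF. The
#' default `p_max` is the Bonferroni correction of 0.05 across the 54,469
#' variants x 4,782 proteins of the pQTL discovery panel.
#'
#' @param s A [summary_stats()] object (the exposure pQTLs).
#' @param p_max Exposure significance threshold.
#' @param f_min F-statistic cutoff (kept instruments have F > `f_min`).
#' @param maf_min MAF cutoff (kept instruments have MAF > `maf_min`).
#' @param missing_eaf Policy when EAF is missing and the MAF filter is
#'   active: `"drop"` (status `removed_maf`) or `"keep"` with a warning.
#' @return data.frame of instrument records: the association fields plus
#'   `f_stat`, `maf`, `status` and `proxy_for`.
#' @export
filter_instruments <- function(s, p_max = 0.05 / 54469 / 4782,
                               f_min = 10, maf_min = 0.001,
                               missing_eaf = c("drop", "keep")) {
  missing_eaf <- match.arg(missing_eaf)
  stopifnot(inherits(s, "summary_stats"))
  assert_scalar_number(p_max, "p_max", 0, 1, open_lower = TRUE)
  assert_scalar_number(f_min, "f_min", 0)
  assert_scalar_number(maf_min, "maf_min", 0, 0.5)
  rec <- s$associations
  rec$f_stat <- f_statistic(rec$beta, rec$se)
  rec$maf <- pmin(rec$eaf, 1 - rec$eaf)
  maf_fail <- if (missing_eaf == "drop") {
    is.na(rec$maf) | rec$maf <= maf_min
  } else {
    if (any(is.na(rec$maf))) {
      pm_log(sum(is.na(rec$maf)), " variant(s) kept with missing EAF ",
             "(MAF filter not applied)")
    }
    !is.na(rec$maf) & rec$maf <= maf_min
  }
  rec$status <- ifelse(rec$pval >= p_max, "removed_p",
                       ifelse(rec$f_stat <= f_min, "removed_f",
                              ifelse(maf_fail, "removed_maf", "kept")))
  rec$proxy_for <- NA_character_
  pm_log(s$trait_name, ": ", sum(rec$status == "kept"), "/", nrow(rec),
         " instruments kept (",
         sum(rec$status == "removed_p"), " p, ",
         sum(rec$status == "removed_f"), " F, ",
         sum(rec$status == "removed_maf"), " MAF removed)")
  rownames(rec) <- NULL
  rec
}

#' Greedy LD pruning of instrument records
#'
#' Orders the kept records by descending F-statistic (ties by variant id)
#' and accepts each unless its r-squared with an already-accepted variant
#' on the same chromosome within `window_bp` exceeds `r2_max`. Rejected
#' records get status `removed_ld`. The result does not depend on the
#' input row order.
#'
#' @param records Output of [filter_instruments()].
#' @param ld An [ld_matrix()]; every same-chromosome pair of kept variants
#'   within the window must have an entry.
#' @param r2_max LD threshold (retained pairs have r-squared <= `r2_max`).
#' @param window_bp Window in base pairs within which LD is enforced.
#' @return `records` with `status` updated.
#' @export
ld_prune <- function(records, ld, r2_max = 0.2, window_bp = 500000) {
  stopifnot(inherits(ld, "ld_matrix"))
  assert_scalar_number(r2_max, "r2_max", 0, 1)
  assert_scalar_number(window_bp, "window_bp", 0)
  cand <- which(records$status == "kept")
  ord <- cand[order(-records$f_stat[cand], records$variant_id[cand])]
  accepted <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in accepted) {
      if (records$chrom[i] != records$chrom[j]) next
      if (abs(records$pos[i] - records$pos[j]) > window_bp) next
      r2 <- ld_lookup(ld, records$variant_id[i], records$variant_id[j])
      if (is.na(r2)) {
        pm_stop(paste0("no LD entry for required pair ",
                       records$variant_id[i], " / ",
                       records$variant_id[j]),
                "protmr_data_completeness_error")
      }
      if (r2 > r2_max) { conflict <- TRUE; break }
    }
    if (conflict) records$status[i] <- "removed_ld"
    else accepted <- c(accepted, i)
  }
  if (length(accepted) < length(cand)) {
    pm_log(length(cand) - length(accepted), " variant(s) removed by LD ",
           "pruning (r2 > ", r2_max, " within ", window_bp, " bp)")
  }
  records
}

#' Find an LD proxy for a variant missing from the outcome
#'
#' Returns the outcome-present variant with maximal r-squared to the
#' target, provided it reaches `r2_proxy_min`; ties are broken by smaller
#' position, then lexicographic id.
#'
#' @param target Variant id absent from the outcome.
#' @param outcome A [summary_stats()] object.
#' @param ld An [ld_matrix()] covering the target and candidates.
#' @param r2_proxy_min Minimum r-squared for a usable proxy.
#' @return The proxy variant id, or `NA_character_` if none qualifies.
#' @export
find_proxy <- function(target, outcome, ld, r2_proxy_min = 0.8) {
  stopifnot(inherits(outcome, "summary_stats"), inherits(ld, "ld_matrix"))
  oa <- outcome$associations
  if (target %in% oa$variant_id) {
    pm_stop(paste0("variant ", target,
                   " is present in the outcome; no proxy needed"),
            "protmr_misuse_error")
  }
  cand <- oa$variant_id[oa$variant_id %in% rownames(ld)]
  if (!target %in% rownames(ld) || length(cand) == 0L) return(NA_character_)
  r2 <- unclass(ld)[target, cand]
  best <- max(r2)
  if (best < r2_proxy_min) return(NA_character_)
  tied <- cand[r2 == best]
  pos <- oa$pos[match(tied, oa$variant_id)]
  tied <- tied[order(pos, tied)]
  tied[1L]
}

#' Substitute proxy outcome records for missing instruments
#'
#' For each exposure instrument absent from the outcome, looks up the best
#' proxy via [find_proxy()] and, when one qualifies, inserts the proxy's
#' outcome estimate relabelled to the target variant (the target's
#' alleles), so that [harmonize()] can pair it. Orientation of the proxy
#' estimate is matched by effect-allele frequency (the closer of EAF and
#' 1-EAF to the exposure EAF); a documented approximation, since r-squared
#' carries no allele sign.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param ld An [ld_matrix()].
#' @param r2_proxy_min Minimum proxy r-squared.
#' @return List with `outcome` (augmented [summary_stats()]) and `proxies`
#'   (data.frame of `target`, `proxy`, `r2`, `flipped`).
#' @export
proxy_outcome <- function(exposure, outcome, ld, r2_proxy_min = 0.8) {
  ea <- exposure$associations
  oa <- outcome$associations
  missing_ids <- setdiff(ea$variant_id, oa$variant_id)
  log <- data.frame(target = character(0), proxy = character(0),
                    r2 = numeric(0), flipped = logical(0),
                    stringsAsFactors = FALSE)
  for (target in missing_ids) {
    proxy <- find_proxy(target, outcome, ld, r2_proxy_min)
    if (is.na(proxy)) next
    row <- oa[oa$variant_id == proxy, , drop = FALSE]
    trow <- ea[ea$variant_id == target, , drop = FALSE]
    flipped <- FALSE
    if (!is.na(row$eaf) && !is.na(trow$eaf)) {
      flipped <- abs((1 - row$eaf) - trow$eaf) < abs(row$eaf - trow$eaf)
    }
    row$variant_id <- target
    row$chrom <- trow$chrom
    row$pos <- trow$pos
    row$effect_allele <- trow$effect_allele
    row$other_allele <- trow$other_allele
    if (flipped) {
      row$beta <- -row$beta
      row$eaf <- 1 - row$eaf
    }
    oa <- rbind(oa, row)
    log <- rbind(log, data.frame(target = target, proxy = proxy,
                                 r2 = ld_lookup(ld, target, proxy),
                                 flipped = flipped,
                                 stringsAsFactors = FALSE))
  }
  if (nrow(log)) {
    pm_log(nrow(log), " proxy variant(s) substituted into the outcome")
  }
  list(outcome = summary_stats(oa, outcome$trait_name, outcome$trait_type,
                               validate = FALSE),
       proxies = log)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two tables on variant id and puts every retained outcome
#' estimate on the exposure's effect-allele orientation. Outcome records
#' with swapped alleles have their beta negated and EAF reflected
#' (`action = "flipped"`). Palindromic variants (A/T or C/G) are handled
#' per `palindromic_policy`: the default `"infer"` drops them when either
#' EAF is missing or inside the ambiguity window and otherwise infers the
#' orientation from EAF agreement; `"drop"` removes all of them; `"keep"`
#' trusts the reported alleles. Variants whose allele sets do not match
#' are dropped with a reason.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param palindromic_policy `"infer"`, `"drop"` or `"keep"`.
#' @param ambiguous_eaf EAF window inside which a palindromic variant is
#'   considered strand-ambiguous under `"infer"`.
#' @return A `harmonized_set`: data.frame with one row per shared variant
#'   (`variant_id`, alleles, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`,
#'   `se_out`, `eaf_out`, `palindromic`, `action`, `reason`), with
#'   `exposure_name`/`outcome_name`/`outcome_type` attributes. Rows with
#'   `action != "dropped"` are the MR input.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("infer", "drop", "keep"),
                      ambiguous_eaf = c(0.42, 0.58)) {
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  ea <- exposure$associations
  oa <- outcome$associations
  shared <- intersect(ea$variant_id, oa$variant_id)
  if (length(shared) == 0L) {
    pm_stop("no shared variants between exposure and outcome",
            "protmr_empty_harmonization_error")
  }
  ea <- ea[match(shared, ea$variant_id), ]
  oa <- oa[match(shared, oa$variant_id), ]

  h <- data.frame(
    variant_id = shared, chrom = ea$chrom, pos = ea$pos,
    effect_allele = ea$effect_allele, other_allele = ea$other_allele,
    beta_exp = ea$beta, se_exp = ea$se, eaf_exp = ea$eaf,
    beta_out = oa$beta, se_out = oa$se, eaf_out = oa$eaf,
    palindromic = is_palindromic(ea$effect_allele, ea$other_allele),
    action = NA_character_, reason = NA_character_,
    stringsAsFactors = FALSE)

  same <- oa$effect_allele == ea$effect_allele &
    oa$other_allele == ea$other_allele
  swapped <- oa$effect_allele == ea$other_allele &
    oa$other_allele == ea$effect_allele
  h$action[same] <- "aligned"
  h$action[swapped] <- "flipped"
  h$beta_out[swapped] <- -h$beta_out[swapped]
  h$eaf_out[swapped] <- 1 - h$eaf_out[swapped]
  bad <- !(same | swapped)
  h$action[bad] <- "dropped"
  h$reason[bad] <- "allele_mismatch"

  pal <- which(h$palindromic & h$action != "dropped")
  if (length(pal)) {
    if (palindromic_policy == "drop") {
      h$action[pal] <- "dropped"
      h$reason[pal] <- "palindromic"
    } else if (palindromic_policy == "infer") {
      for (i in pal) {
        ambiguous <- is.na(h$eaf_exp[i]) || is.na(h$eaf_out[i]) ||
          (h$eaf_exp[i] > ambiguous_eaf[1] & h$eaf_exp[i] < ambiguous_eaf[2]) ||
          (h$eaf_out[i] > ambiguous_eaf[1] & h$eaf_out[i] < ambiguous_eaf[2])
        if (ambiguous) {
          h$action[i] <- "dropped"
          h$reason[i] <- "ambiguous_palindromic"
        } else if ((h$eaf_exp[i] - 0.5) * (h$eaf_out[i] - 0.5) < 0) {
          # frequencies disagree after nominal alignment: strand flip
          h$beta_out[i] <- -h$beta_out[i]
          h$eaf_out[i] <- 1 - h$eaf_out[i]
          h$action[i] <- if (h$action[i] == "aligned") "flipped" else "aligned"
        }
      }
    }
  }
  dropped <- sum(h$action == "dropped")
  if (dropped) pm_log(dropped, " variant(s) dropped during harmonization")
  if (dropped == nrow(h)) {
    pm_stop("no variants survive harmonization",
            "protmr_empty_harmonization_error")
  }
  structure(h, class = c("harmonized_set", "data.frame"),
            exposure_name = exposure$trait_name,
            outcome_name = outcome$trait_name,
            outcome_type = outcome$trait_type)
}

# Retained rows of a harmonized set (the MR input).
h_kept <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  h[h$action != "dropped", , drop = FALSE]
}
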