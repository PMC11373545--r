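VALID_ALLELES <- c("A", "C", "G", "T")

ASSOC_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pval", "n")

#' Construct a summary-statistics object
#'
#' Container for one trait's per-variant association estimates: the unit of
#' exchange between instrument selection, harmonization and the MR
#' estimators. Each row holds one variant's effect estimate (beta per copy
#' of the effect allele), its standard error, p-value, effect-allele
#' frequency and sample size.
#'
#' @param associations data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`
#'   (`eaf` and `n` may be `NA`).
#' @param trait_name Trait label (e.g. protein or disease name).
#' @param trait_type `"continuous"` (betas in SD units) or `"binary"`
#'   (betas are log-odds).
#' @param validate Drop rows violating field constraints (logged) instead of
#'   erroring. Always enforces unique, non-empty variant ids.
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(associations, trait_name,
                          trait_type = c("continuous", "binary"),
                          validate = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(associations)) {
    pm_stop("'associations' must be a data.frame", "protmr_format_error")
  }
  missing_cols <- setdiff(ASSOC_COLUMNS, names(associations))
  if (length(missing_cols)) {
    pm_stop(paste0("missing association column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "protmr_format_error")
  }
  a <- associations[ASSOC_COLUMNS]
  a$variant_id <- as.character(a$variant_id)
  a$chrom <- as.character(a$chrom)
  a$pos <- as.integer(a$pos)
  a$effect_allele <- toupper(as.character(a$effect_allele))
  a$other_allele <- toupper(as.character(a$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) a[[col]] <- as.numeric(a[[col]])
  a$n <- as.numeric(a$n)

  if (validate) {
    ok <- !is.na(a$variant_id) & nzchar(a$variant_id) &
      a$effect_allele %in% VALID_ALLELES &
      a$other_allele %in% VALID_ALLELES &
      a$effect_allele != a$other_allele &
      is.finite(a$beta) & is.finite(a$se) & a$se > 0 &
      is.finite(a$pval) & a$pval > 0 & a$pval <= 1 &
      (is.na(a$eaf) | (a$eaf > 0 & a$eaf < 1)) &
      (is.na(a$n) | a$n > 0)
    ok[is.na(ok)] <- FALSE
    if (any(!ok)) {
      pm_log(sum(!ok), " association row(s) dropped for failing validation (",
             trait_name, ")")
      a <- a[ok, , drop = FALSE]
    }
    # beta/se vs p consistency is warn-only: published tables round p-values.
    p_implied <- two_sided_p(a$beta / a$se)
    inconsistent <- is.finite(p_implied) & p_implied > 0 &
      (a$pval / p_implied > 2 | a$pval / p_implied < 0.5) &
      a$pval > 1e-300
    if (any(inconsistent)) {
      pm_log(sum(inconsistent), " row(s) with p-value inconsistent with ",
             "beta/se beyond factor 2 (kept; ", trait_name, ")")
    }
  }
  if (nrow(a) == 0L) {
    pm_stop(paste0("no valid associations for trait '", trait_name, "'"),
            "protmr_empty_input_error")
  }
  if (anyDuplicated(a$variant_id)) {
    pm_stop("duplicate variant_id within a summary_stats object",
            "protmr_format_error")
  }
  rownames(a) <- NULL
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 associations = a),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: %s (%s), %d variants\n",
              x$trait_name, x$trait_type, nrow(x$associations)))
  print(head(x$associations, 5L))
  invisible(x)
}

n_variants <- function(s) nrow(s$associations)

#' Construct an LD matrix
#'
#' Square matrix of pairwise r-squared between variants, keyed by variant
#' id. Used for local LD pruning and proxy lookup in place of remote LD
#' services.
#'
#' @param r2 Square numeric matrix of r-squared values in \[0, 1\].
#' @param variant_ids Variant ids; defaults to `rownames(r2)`.
#' @return An object of class `ld_matrix` (a matrix with id dimnames).
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(variant_ids) || length(variant_ids) != nrow(r2)) {
    pm_stop("'variant_ids' must label every row of the LD matrix",
            "protmr_format_error")
  }
  if (nrow(r2) != ncol(r2)) {
    pm_stop("LD matrix must be square", "protmr_format_error")
  }
  if (anyDuplicated(variant_ids)) {
    pm_stop("duplicate variant ids in LD matrix", "protmr_format_error")
  }
  storage.mode(r2) <- "double"
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    pm_stop("LD r-squared values must lie in [0, 1]", "protmr_format_error")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) {
    pm_stop("LD matrix must be symmetric (tolerance 1e-8)",
            "protmr_format_error")
  }
  if (any(abs(diag(r2) - 1) > 1e-12)) {
    pm_stop("LD matrix diagonal must equal 1", "protmr_format_error")
  }
  dimnames(r2) <- list(variant_ids, variant_ids)
  class(r2) <- c("ld_matrix", "matrix", "array")
  r2
}

ld_lookup <- function(ld, id1, id2) {
  if (!(id1 %in% rownames(ld)) || !(id2 %in% rownames(ld))) return(NA_real_)
  unclass(ld)[id1, id2]
}

#' Construct an expression matrix
#'
#' Protein-array intensities (proteins x samples, linear scale) with a
#' two-group case/control design, the input of the differential-expression
#' screen.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns, with
#'   dimnames; all values finite and nonnegative.
#' @param group Character/factor of per-sample labels in
#'   `c("case", "control")`, in column order or named by sample id.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, group) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    pm_stop("expression matrix needs protein rownames and sample colnames",
            "protmr_format_error")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    pm_stop("duplicate protein or sample ids", "protmr_format_error")
  }
  if (any(!is.finite(values))) {
    pm_stop("expression intensities must all be finite", "protmr_range_error")
  }
  if (any(values < 0)) {
    pm_stop("negative expression intensity", "protmr_range_error")
  }
  if (!is.null(names(group))) {
    if (!setequal(names(group), colnames(values))) {
      pm_stop("group labels do not match matrix sample ids",
              "protmr_consistency_error")
    }
    group <- group[colnames(values)]
  } else if (length(group) != ncol(values)) {
    pm_stop("one group label per sample is required",
            "protmr_consistency_error")
  }
  group <- as.character(group)
  if (!all(group %in% c("case", "control"))) {
    pm_stop("group labels must be 'case' or 'control'",
            "protmr_format_error")
  }
  if (sum(group == "case") < 2L || sum(group == "control") < 2L) {
    pm_stop("both groups need at least 2 samples", "protmr_invariant_error")
  }
  structure(list(values = values,
                 group = setNames(group, colnames(values))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d proteins x %d samples (%d case / %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}
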