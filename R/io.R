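# File dialect shared by all readers/writers: tab-separated, UTF-8,
# '#'-prefixed comment lines, 'NA' as the missing token.

#' Default summary-statistics column mapping
#'
#' Maps the canonical internal field names to file header names. The
#' defaults follow common GWAS summary-stat exports (SNP, CHR, POS, EA, OA,
#' EAF, BETA, SE, P, N); override entries to ingest other dialects.
#'
#' @param ... Named overrides, e.g. `sumstats_columns(variant_id = "rsid")`.
#' @return Named character vector mapping internal names to header names.
#' @export
sumstats_columns <- function(...) {
  map <- c(variant_id = "SNP", chrom = "CHR", pos = "POS",
           effect_allele = "EA", other_allele = "OA", eaf = "EAF",
           beta = "BETA", se = "SE", pval = "P", n = "N")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad)) {
      pm_stop(paste0("unknown column-map field(s): ",
                     paste(bad, collapse = ", ")), "protmr_format_error")
    }
    map[names(over)] <- over
  }
  map
}

# colClasses = "character" protects allele columns: a column of all T
# would otherwise be read as logical.
read_tsv_commented <- function(path, colClasses = NA) {
  if (!file.exists(path)) {
    pm_stop(paste0("file not found: ", path), "protmr_io_error")
  }
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = "NA", fileEncoding = "UTF-8",
             colClasses = colClasses)
}

#' Read GWAS/pQTL summary statistics
#'
#' Reads a tab-separated association table into a [summary_stats()] object.
#' Rows failing field validation (non-ACGT or identical alleles,
#' non-positive SE, p outside (0, 1\], EAF outside (0, 1)) are dropped with a
#' logged count; alleles are uppercased on ingest.
#'
#' @param path Path to a TSV file ('#' comment lines allowed).
#' @param column_map Mapping from internal field names to file headers, see
#'   [sumstats_columns()].
#' @param trait_name Trait label; defaults to the file name.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return A [summary_stats()] object.
#' @export
read_sumstats <- function(path, column_map = sumstats_columns(),
                          trait_name = NULL,
                          trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  trait_name <- trait_name %||% sub("\\.[^.]*$", "", basename(path))
  tab <- read_tsv_commented(path, colClasses = "character")
  mandatory <- setdiff(names(column_map), c("eaf", "n"))
  missing_cols <- column_map[mandatory][!(column_map[mandatory] %in% names(tab))]
  if (length(missing_cols)) {
    pm_stop(paste0("summary-statistics file ", path,
                   " is missing mandatory column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "protmr_format_error")
  }
  out <- data.frame(row.names = seq_len(nrow(tab)))
  for (field in names(column_map)) {
    col <- column_map[[field]]
    out[[field]] <- if (col %in% names(tab)) tab[[col]] else NA
  }
  summary_stats(out, trait_name = trait_name, trait_type = trait_type)
}

#' Write summary statistics to a TSV file
#'
#' Inverse of [read_sumstats()]: `read_sumstats(write_sumstats(s, path))`
#' reproduces `s` field for field. Missing EAF/N are written as `NA`.
#'
#' @param s A [summary_stats()] object.
#' @param path Output path.
#' @param column_map Header names to write, see [sumstats_columns()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path, column_map = sumstats_columns()) {
  stopifnot(inherits(s, "summary_stats"))
  if (nrow(s$associations) == 0L) {
    pm_stop("refusing to write an empty summary_stats object",
            "protmr_empty_input_error")
  }
  tab <- s$associations
  names(tab) <- column_map[names(tab)]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# trait_name=", s$trait_name,
                    " trait_type=", s$trait_type), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a local LD matrix
#'
#' Reads a square tab-separated r-squared table (variant ids in the first
#' row and first column, the plink `--r2 square` layout) into an
#' [ld_matrix()]. Asymmetries beyond 1e-8, off-range entries and a
#' non-unit diagonal are rejected.
#'
#' @param path Path to the TSV file.
#' @return An [ld_matrix()] object.
#' @export
read_ld_matrix <- function(path) {
  tab <- read_tsv_commented(path)
  if (ncol(tab) < 2L) {
    pm_stop("LD matrix file must have an id column plus numeric columns",
            "protmr_format_error")
  }
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!identical(colnames(m), ids)) {
    pm_stop("LD matrix row and column ids disagree (non-square layout?)",
            "protmr_format_error")
  }
  ld_matrix(m, ids)
}

#' Write an LD matrix to a TSV file
#'
#' @param ld An [ld_matrix()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  tab <- data.frame(variant_id = rownames(ld), unclass(ld),
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein expression matrix with sample groups
#'
#' @param matrix_path Delimited text file, proteins x samples, protein id in
#'   the first column, sample ids in the header.
#' @param groups_path Two-column TSV (`sample_id`, `group`), group in
#'   `c("case", "control")`; must cover exactly the matrix samples.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(matrix_path, groups_path) {
  tab <- read_tsv_commented(matrix_path)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- as.character(tab[[1L]])
  grp <- read_tsv_commented(groups_path)
  if (!all(c("sample_id", "group") %in% names(grp))) {
    pm_stop("groups file needs columns 'sample_id' and 'group'",
            "protmr_format_error")
  }
  if (!setequal(grp$sample_id, colnames(values))) {
    pm_stop("sample ids in groups file do not match the matrix columns",
            "protmr_consistency_error")
  }
  expression_matrix(values, setNames(grp$group, grp$sample_id))
}

#' Write an expression matrix and its groups table
#'
#' @param m An [expression_matrix()] object.
#' @param matrix_path,groups_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(m, matrix_path, groups_path) {
  stopifnot(inherits(m, "expression_matrix"))
  tab <- data.frame(protein_id = rownames(m$values), m$values,
                    check.names = FALSE)
  write.table(tab, matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  write.table(data.frame(sample_id = names(m$group), group = m$group),
              groups_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(matrix_path)
}
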