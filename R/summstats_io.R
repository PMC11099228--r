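# Reading, validating, and writing GWAS summary-statistic tables and LD
# matrices. All tabular input enters the package through this file.

#' Canonical summary-statistic column names
#'
#' The default column dialect: `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`. Files in other dialects
#' are accommodated through the `column_map` argument of
#' [read_summary_stats()].
#'
#' @export
summstat_columns <- function() {
  c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pvalue", "n")
}

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a validated summary dataset
#'
#' A summary dataset is a data frame of per-variant associations for one
#' trait, one row per SNP, with columns [summstat_columns()]. Rows violating
#' hard invariants (non-ACGT or identical alleles, `se <= 0`, `eaf` outside
#' \[0,1\], `pvalue` outside (0,1\], non-positive `n`, non-finite `beta`,
#' duplicated `snp_id`) are dropped with a message giving the count. Alleles
#' are upper-cased before validation. A soft check compares the reported
#' p-value with the Wald p implied by `beta/se` and warns when they disagree
#' by more than two orders of magnitude.
#'
#' @param records data frame with the columns of [summstat_columns()].
#' @param trait_id short machine identifier for the trait.
#' @param trait_label human-readable label; defaults to `trait_id`.
#' @param trait_scale `"log_odds"` for binary traits (betas are log odds
#'   ratios) or `"continuous"` (betas in SD units).
#' @param quiet suppress the dropped-row message.
#' @return A `summary_dataset`: the validated data frame with attributes
#'   `trait_id`, `trait_label`, `trait_scale`, and `n_dropped`.
#' @export
summary_dataset <- function(records, trait_id, trait_label = trait_id,
                            trait_scale = c("continuous", "log_odds"),
                            quiet = FALSE) {
  trait_scale <- match.arg(trait_scale)
  missing_cols <- setdiff(summstat_columns(), names(records))
  if (length(missing_cols) > 0) {
    config_error(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  records <- as.data.frame(records)[summstat_columns()]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  ok <- !is.na(records$snp_id) & nzchar(records$snp_id) &
    records$effect_allele %in% VALID_ALLELES &
    records$other_allele %in% VALID_ALLELES &
    records$effect_allele != records$other_allele &
    is.finite(records$beta) &
    is.finite(records$se) & records$se > 0 &
    is.finite(records$eaf) & records$eaf >= 0 & records$eaf <= 1 &
    is.finite(records$pvalue) & records$pvalue > 0 & records$pvalue <= 1 &
    is.finite(records$n) & records$n > 0 &
    is.finite(records$pos) & records$pos >= 1
  ok[is.na(ok)] <- FALSE
  ok <- ok & !duplicated(records$snp_id)

  n_dropped <- sum(!ok)
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (n_dropped > 0 && !quiet) {
    message(sprintf("summary_dataset('%s'): dropped %d invalid record(s)",
                    trait_id, n_dropped))
  }

  # Soft consistency check: reported p vs normal Wald p from |beta/se|.
  if (nrow(out) > 0) {
    implied <- z_to_p(out$beta / out$se)
    off <- abs(log10(pmax(implied, 1e-300)) - log10(pmax(out$pvalue, 1e-300)))
    if (any(off > 2, na.rm = TRUE)) {
      warning(sprintf(
        "summary_dataset('%s'): %d record(s) have p-values >2 orders of magnitude from the Wald p implied by beta/se",
        trait_id, sum(off > 2, na.rm = TRUE)), call. = FALSE)
    }
  }

  structure(out,
            trait_id = trait_id,
            trait_label = trait_label,
            trait_scale = trait_scale,
            n_dropped = n_dropped,
            class = c("summary_dataset", "data.frame"))
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> trait '%s' (%s scale): %d variant(s)\n",
              attr(x, "trait_id"), attr(x, "trait_scale"), nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more row(s)\n", nrow(x) - 6))
  invisible(x)
}

trait_id <- function(ds) attr(ds, "trait_id") %||% "trait"

# Rebuild a summary_dataset after row subsetting, preserving trait metadata.
reindex_dataset <- function(ds, keep) {
  d <- as.data.frame(ds)[keep, , drop = FALSE]
  rownames(d) <- NULL
  structure(d,
            trait_id = attr(ds, "trait_id"),
            trait_label = attr(ds, "trait_label"),
            trait_scale = attr(ds, "trait_scale"),
            n_dropped = attr(ds, "n_dropped"),
            class = c("summary_dataset", "data.frame"))
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated file with a header row into a validated
#' [summary_dataset()]. Columns named differently from [summstat_columns()]
#' are renamed through `column_map`, a named character vector mapping
#' canonical names to the file's column names, e.g.
#' `c(snp_id = "SNP", pvalue = "P")`.
#'
#' @param path file path.
#' @param trait_id trait identifier; defaults to the file name sans extension.
#' @param column_map optional named character vector (canonical -> file).
#' @inheritParams summary_dataset
#' @return A [summary_dataset()].
#' @export
read_summary_stats <- function(path, trait_id = NULL, column_map = NULL,
                               trait_label = NULL,
                               trait_scale = c("continuous", "log_odds"),
                               quiet = FALSE) {
  trait_scale <- match.arg(trait_scale)
  if (!file.exists(path)) io_error(paste0("file not found: ", path))
  if (file.size(path) == 0) input_error(paste0("empty file: ", path))
  # colClasses = "character": a bare T/F allele must never parse as logical
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        config_error(paste0("column_map names missing column '", src,
                            "' (for '", canon, "')"))
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(summstat_columns(), names(df))
  if (length(missing_cols) > 0) {
    config_error(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (is.null(trait_id)) {
    trait_id <- sub("\\.[^.]*$", "", basename(path))
  }
  summary_dataset(df, trait_id = trait_id,
                  trait_label = trait_label %||% trait_id,
                  trait_scale = trait_scale, quiet = quiet)
}

#' Write a summary dataset to a tab-separated file
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_summary_stats(write_summary_stats(ds))` reproduces `ds` exactly
#' field for field. An empty dataset produces a header-only file.
#'
#' @param ds a [summary_dataset()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ds, path) {
  cols <- summstat_columns()
  out <- data.frame(
    snp_id = as.character(ds$snp_id),
    chrom = as.character(ds$chrom),
    pos = format_full(ds$pos),
    effect_allele = ds$effect_allele,
    other_allele = ds$other_allele,
    eaf = format_full(ds$eaf),
    beta = format_full(ds$beta),
    se = format_full(ds$se),
    pvalue = format_full(ds$pvalue),
    n = format_full(ds$n),
    stringsAsFactors = FALSE
  )
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(out) > 0) do.call(paste, c(out, sep = "\t")))
  status <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(status)) {
    io_error(paste0("cannot write to '", path, "': ",
                    conditionMessage(status)))
  }
  invisible(path)
}

#' Read a labeled LD (r-squared) matrix
#'
#' Expects a tab-separated square numeric table whose header and first column
#' hold matching SNP labels. Values must lie in \[0,1\]; asymmetry beyond
#' 1e-6 or a diagonal away from 1 is an input error. The returned matrix is
#' exactly symmetrized with a unit diagonal.
#'
#' @param path file path.
#' @return A symmetric numeric matrix with SNP-labeled dimnames.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) io_error(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
}

#' Validate an LD matrix given as an R matrix
#'
#' @param m square numeric matrix with matching row/column names.
#' @return The validated, exactly symmetrized matrix.
#' @export
validate_ld_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    input_error("LD matrix must be square")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    input_error("LD matrix row and column SNP labels must match")
  }
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    input_error("LD r-squared values must lie in [0, 1]")
  }
  if (max(abs(m - t(m))) > 1e-6) {
    input_error("LD matrix asymmetric beyond 1e-6")
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    input_error("LD matrix diagonal must be 1")
  }
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Write an LD matrix as a labeled tab-separated table
#'
#' @param m symmetric numeric matrix with SNP-labeled dimnames.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(m, path) {
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format_full(m[i, ])), collapse = "\t")
  }, character(1))
  lines <- c(paste(c("snp_id", colnames(m)), collapse = "\t"), rows)
  tryCatch(writeLines(lines, path),
           error = function(e) io_error(paste0("cannot write to '", path, "'")))
  invisible(path)
}

# r2 lookup with absent-SNP-independent semantics used by clumping.
ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) return(0)
  ia <- match(a, rownames(ld))
  ib <- match(b, colnames(ld))
  if (is.na(ia) || is.na(ib)) return(0)
  ld[ia, ib]
}
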