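#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column is `gene_id` and whose
#' remaining columns are sample IDs; values must parse as non-negative
#' reals. Malformed input (ragged rows, duplicate gene or sample IDs,
#' negative or non-numeric values) is rejected, never coerced.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene IDs as rownames, sample IDs as colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    read.delim(path,
      header = TRUE, sep = "\t", check.names = FALSE,
      colClasses = "character", comment.char = ""
    ),
    error = function(e) stopf("failed to parse '%s': %s", path, conditionMessage(e))
  )
  if (ncol(df) < 2) stopf("expression TSV needs a gene_id column plus samples")
  if (names(df)[1] != "gene_id") {
    stopf("first column of expression TSV must be 'gene_id'")
  }
  genes <- df[[1]]
  if (any(genes == "" | is.na(genes))) stopf("empty gene ID in '%s'", path)
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stopf("duplicate gene ID(s) in '%s': %s", path, paste(unique(dup), collapse = ", "))
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) stopf("duplicate sample IDs in '%s'", path)
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(genes, samples))
  if (any(is.na(vals))) stopf("non-numeric expression value in '%s'", path)
  if (any(vals < 0)) stopf("negative expression value in '%s'", path)
  vals
}

#' Write an expression matrix as TSV
#'
#' @param E genes x samples numeric matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(E, path) {
  check_expression_matrix(E)
  if (any(grepl("[\t\n ]", c(rownames(E), colnames(E))))) {
    stopf("gene/sample IDs must not contain whitespace")
  }
  df <- data.frame(gene_id = rownames(E), E, check.names = FALSE)
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Requires columns `sample_id, subject_id, region, diagnosis`; the optional
#' columns `age, sex, apoe4, braak` are typed when present. Diagnosis labels
#' are normalized to `AD` / `control` (case-insensitive; `CTRL`, `CT`,
#' `healthy` map to control). Unknown region labels are kept as-is.
#'
#' @param path path to the CSV file.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0) stopf("metadata file '%s' is empty", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stopf("metadata file '%s' has no rows", path)
  req <- c("sample_id", "subject_id", "region", "diagnosis")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stopf("metadata missing required column(s): %s", paste(missing, collapse = ", "))
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stopf("duplicate sample_id(s) in '%s': %s", path, paste(unique(dup), collapse = ", "))
  }
  dx <- tolower(df$diagnosis)
  norm <- ifelse(dx == "ad", "AD",
    ifelse(dx %in% c("control", "ctrl", "ct", "healthy"), "control", NA)
  )
  if (anyNA(norm)) {
    stopf(
      "unrecognized diagnosis label(s): %s",
      paste(unique(df$diagnosis[is.na(norm)]), collapse = ", ")
    )
  }
  df$diagnosis <- norm
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  if ("apoe4" %in% names(df)) df$apoe4 <- as.integer(df$apoe4)
  if ("braak" %in% names(df)) df$braak <- as.integer(df$braak)
  df
}

#' Write sample metadata as CSV
#'
#' @param meta metadata data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_metadata <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth table written by [write_fixture()]
#'
#' @param path path to the truth CSV (`gene_id, is_de, true_logfc`).
#' @return data.frame.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "is_de", "true_logfc")
  if (!all(req %in% names(df))) {
    stopf("truth table must have columns %s", paste(req, collapse = ", "))
  }
  df$is_de <- as.logical(df$is_de)
  df
}

#' Read a gene-set collection from a GMT file
#'
#' Broad-convention GMT: one set per line, tab-separated
#' `name <TAB> description <TAB> member <TAB> member ...`. Member lists are
#' deduplicated within each set; set order is preserved; duplicate set names
#' and lines with fewer than three fields are errors.
#'
#' @param path path to the GMT file.
#' @return named list of sets; each element is a list with `description`
#'   and `genes` (unique character vector). Class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stopf("GMT line %d has fewer than 3 fields", short[1])
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  dup <- names_[duplicated(names_)]
  if (length(dup)) {
    stopf("duplicate gene-set name(s): %s", paste(unique(dup), collapse = ", "))
  }
  sets <- lapply(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stopf("gene set '%s' is empty", f[[1]])
    list(description = f[[2]], genes = genes)
  })
  names(sets) <- names_
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets a `gene_set_collection` or named list of character vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) s <- list(description = "na", genes = s)
    paste(c(names(sets)[i], s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Extract plain member lists from a gene-set collection
#'
#' @param sets a `gene_set_collection`.
#' @return named list of character vectors.
#' @export
gene_set_members <- function(sets) {
  lapply(sets, function(s) if (is.character(s)) s else s$genes)
}

#' Write a differential-expression results table as CSV
#'
#' Optionally prefixes provenance comment lines (starting with `#`);
#' [read_de_table()] skips them.
#'
#' @param de data.frame of per-gene results.
#' @param path output path.
#' @param comments character vector of comment lines (without the leading
#'   `#`), or NULL.
#' @return invisibly, `path`.
#' @export
write_de_table <- function(de, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  write.csv(de, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a differential-expression results table written by [write_de_table()]
#'
#' @param path path to the CSV.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
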