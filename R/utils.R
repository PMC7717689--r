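stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that an object is a valid expression matrix
#'
#' A valid expression matrix is numeric, has unique non-empty rownames
#' (gene IDs) and colnames (sample IDs), and contains only finite values.
#'
#' @param E matrix to validate.
#' @param non_negative require all values `>= 0` (TRUE for FPKM-scale input,
#'   FALSE for log2-scale matrices).
#' @return `E`, invisibly, after validation.
#' @keywords internal
check_expression_matrix <- function(E, non_negative = FALSE) {
  if (!is.matrix(E) || !is.numeric(E)) {
    stopf("expression data must be a numeric matrix")
  }
  if (is.null(rownames(E)) || anyDuplicated(rownames(E))) {
    stopf("expression matrix must have unique gene IDs as rownames")
  }
  if (is.null(colnames(E)) || anyDuplicated(colnames(E))) {
    stopf("expression matrix must have unique sample IDs as colnames")
  }
  if (any(!is.finite(E))) stopf("expression matrix contains non-finite values")
  if (non_negative && any(E < 0)) {
    stopf("expression matrix contains negative values")
  }
  invisible(E)
}

check_meta_matches <- function(E, meta) {
  if (!identical(sort(colnames(E)), sort(meta$sample_id))) {
    stopf("sample IDs of expression matrix and metadata do not match")
  }
  invisible(TRUE)
}

# align metadata rows to the column order of an expression matrix
align_meta <- function(E, meta) {
  check_meta_matches(E, meta)
  meta[match(colnames(E), meta$sample_id), , drop = FALSE]
}

# numeric 0/1 encoding of sex, female = 1
encode_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- ifelse(s %in% c("f", "female", "1"), 1,
    ifelse(s %in% c("m", "male", "0"), 0, NA_real_)
  )
  if (anyNA(out)) stopf("sex column contains values other than F/M (or 1/0)")
  out
}

# deterministic small-integer hash of an R object, for provenance headers
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  ints <- utf8ToInt(txt)
  h <- 0
  for (i in ints) h <- (h * 31 + i) %% 2147483647
  sprintf("%08x", h)
}
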