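#' Fixed-effect specification for the differential-expression model
#'
#' The model of interest contrasts AD against control; region can optionally
#' enter as a fixed effect. The same fixed-effect structure is used by the
#' unweighted first pass that feeds the mean-variance trend and by the
#' per-gene mixed model.
#'
#' @param region_effect include region as a fixed effect (default FALSE; the
#'   contrast of interest is disease status).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(region_effect = FALSE) {
  structure(list(region_effect = isTRUE(region_effect)), class = "model_spec")
}

#' Build the fixed-effect design matrix for a metadata table
#'
#' Columns: intercept, `diagnosisAD` (1 for AD), and treatment-coded region
#' dummies when `spec$region_effect` is TRUE. The diagnosis column is always
#' column 2, so its coefficient is the log2 fold change AD vs control.
#'
#' @param meta sample metadata.
#' @param spec a [model_spec()].
#' @return numeric design matrix with one row per sample.
#' @export
build_design <- function(meta, spec = model_spec()) {
  if (!all(meta$diagnosis %in% c("AD", "control"))) {
    stopf("diagnosis must be 'AD' or 'control'")
  }
  X <- cbind(
    `(Intercept)` = rep(1, nrow(meta)),
    diagnosisAD = as.numeric(meta$diagnosis == "AD")
  )
  if (isTRUE(spec$region_effect)) {
    regions <- sort(unique(meta$region))
    if (length(regions) > 1) {
      for (r in regions[-1]) {
        X <- cbind(X, as.numeric(meta$region == r))
        colnames(X)[ncol(X)] <- paste0("region", r)
      }
    }
  }
  if (qr(X)$rank < ncol(X)) stopf("fixed-effect design is singular")
  X
}
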