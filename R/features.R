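# Feature construction: raw biophysics -> centred, scaled (log Cm, log Rm, Vm)

.feature_names <- c("log_cm", "log_rm", "vm")

#' Fit feature standardization parameters
#'
#' Computes the centring and scaling used by the classifier. The raw feature
#' triple is (log Cm, log Rm, Vm) in that fixed order, matching the order of
#' the model's slope coefficients; logs are natural, which is immaterial
#' because any base change is an affine map absorbed by standardization.
#' Means and standard deviations are computed over the supplied records —
#' normally all QC-passing cells of one genotype, so each genotype's model is
#' self-contained.
#'
#' @param records a `cell_records` table with at least 2 rows.
#' @param sd_denom `"n-1"` (sample sd, default) or `"n"` (population sd);
#'   both variants are supported because either convention could have been
#'   used upstream and the fitted coefficients differ slightly between them.
#' @return a `standardization_params` object: `means`, `sds` (named
#'   3-vectors over `log_cm`, `log_rm`, `vm`), `genotype`, `n_cells`,
#'   `sd_denom`.
#' @export
fit_standardization <- function(records, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  records <- validate_cell_records(records)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to fit standardization", call. = FALSE)
  raw <- cbind(log_cm = log(records$cm), log_rm = log(records$rm),
               vm = records$vm)
  means <- colMeans(raw)
  sds <- apply(raw, 2, stats::sd)
  if (sd_denom == "n") sds <- sds * sqrt((n - 1) / n)
  degenerate <- sds <= 0 | !is.finite(sds)
  if (any(degenerate)) {
    stop("zero sample variance in feature(s): ",
         paste(.feature_names[degenerate], collapse = ", "), call. = FALSE)
  }
  geno <- unique(records$genotype)
  structure(
    list(means = means, sds = sds,
         genotype = if (length(geno) == 1L) geno else "pooled",
         n_cells = n, sd_denom = sd_denom),
    class = "standardization_params"
  )
}

#' Apply a fitted standardization to cell records
#'
#' Maps each record to the dimensionless feature vector
#' `x = ((log cm - mean1)/sd1, (log rm - mean2)/sd2, (vm - mean3)/sd3)`.
#'
#' @param params a `standardization_params` object.
#' @param records a `cell_records` table.
#' @param check_genotype error if the records' genotype differs from the one
#'   the parameters were fitted under (default `TRUE`); set `FALSE` to apply
#'   a model across genotypes deliberately.
#' @return numeric matrix with one row per record and columns `x1, x2, x3`.
#' @export
apply_standardization <- function(params, records, check_genotype = TRUE) {
  stopifnot(inherits(params, "standardization_params"))
  records <- validate_cell_records(records)
  if (check_genotype && params$genotype %in% .genotypes &&
      !all(records$genotype == params$genotype)) {
    stop("genotype mismatch: params fitted on ", params$genotype,
         " but records contain other genotypes ",
         "(use check_genotype = FALSE to override)", call. = FALSE)
  }
  raw <- cbind(log(records$cm), log(records$rm), records$vm)
  x <- sweep(sweep(raw, 2, params$means, "-"), 2, params$sds, "/")
  colnames(x) <- c("x1", "x2", "x3")
  rownames(x) <- records$cell_id
  if (!all(is.finite(x))) stop("non-finite standardized features", call. = FALSE)
  x
}

#' Serialize standardization parameters to a list (for JSON/YAML reports)
#' @param params a `standardization_params` object.
#' @return plain named list.
#' @export
standardization_as_list <- function(params) {
  stopifnot(inherits(params, "standardization_params"))
  list(means = as.list(params$means), sds = as.list(params$sds),
       genotype = params$genotype, n_cells = params$n_cells,
       sd_denom = params$sd_denom)
}

#' Rebuild standardization parameters from a serialized list
#' @param x list as produced by [standardization_as_list()].
#' @return a `standardization_params` object.
#' @export
standardization_from_list <- function(x) {
  means <- unlist(x$means)[.feature_names]
  sds <- unlist(x$sds)[.feature_names]
  if (any(is.na(means)) || any(is.na(sds)) || any(sds <= 0)) {
    stop("invalid serialized standardization parameters", call. = FALSE)
  }
  structure(
    list(means = means, sds = sds, genotype = x$genotype,
         n_cells = as.integer(x$n_cells), sd_denom = x$sd_denom),
    class = "standardization_params"
  )
}
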