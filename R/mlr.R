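# Multinomial logistic regression over (x1, x2, x3) with three cell-type
# classes. Class coding is fixed: type1 is the reference (logit 0), the two
# modelled contrasts are type2a-vs-type1 and type2b-vs-type1, and each
# contrast has coefficients (intercept, x1, x2, x3) over the standardized
# (log Cm, log Rm, Vm) features.

.contrast_names <- c("type2a", "type2b")
.term_names <- c("intercept", "x1", "x2", "x3")

.as_beta <- function(beta) {
  beta <- as.matrix(beta)
  if (!identical(dim(beta), c(2L, 4L)) || !all(is.finite(beta))) {
    stop("beta must be a finite 2x4 matrix (contrasts x terms)", call. = FALSE)
  }
  dimnames(beta) <- list(.contrast_names, .term_names)
  beta
}

.as_label_index <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    idx <- match(labels, .cell_types)
    if (anyNA(idx)) stop("labels must be in ", paste(.cell_types, collapse = ", "),
                         call. = FALSE)
    return(idx)
  }
  if (is.numeric(labels) && all(labels %in% 0:2)) return(as.integer(labels) + 1L)
  stop("labels must be type names or integer codes 0 (type1), 1 (type2a), 2 (type2b)",
       call. = FALSE)
}

.as_feature_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  x <- as.matrix(x)
  if (ncol(x) != 3L || !all(is.finite(x))) {
    stop("features must be finite with 3 columns (x1, x2, x3)", call. = FALSE)
  }
  x
}

# Row-wise log-sum-exp of the 3-column logit matrix; stable for |logit|
# up to well beyond 700.
.row_lse <- function(eta) {
  m <- pmax(eta[, 1L], eta[, 2L], eta[, 3L])
  m + log(exp(eta[, 1L] - m) + exp(eta[, 2L] - m) + exp(eta[, 3L] - m))
}

.logits <- function(beta, x) {
  z <- cbind(1, x)
  cbind(type1 = 0, z %*% t(beta))
}

.softmax_probs <- function(beta, x) {
  eta <- .logits(beta, x)
  p <- exp(eta - .row_lse(eta))
  colnames(p) <- .cell_types
  p
}

#' Multinomial log-likelihood
#'
#' Sum over cells of the log probability of the observed class under the
#' softmax implied by `beta`, computed with log-sum-exp stabilization.
#'
#' @param beta 2x4 coefficient matrix (rows: type2a, type2b contrasts;
#'   columns: intercept, x1, x2, x3).
#' @param x feature matrix (n x 3) of standardized (log Cm, log Rm, Vm).
#' @param labels class labels: type names, factor, or integer codes 0/1/2.
#' @return scalar log-likelihood.
#' @export
mlr_log_likelihood <- function(beta, x, labels) {
  beta <- .as_beta(beta)
  x <- .as_feature_matrix(x)
  y <- .as_label_index(labels)
  if (nrow(x) == 0L || length(y) == 0L) stop("empty data", call. = FALSE)
  if (nrow(x) != length(y)) stop("features and labels differ in length", call. = FALSE)
  .ll_idx(beta, x, y)
}

# log-likelihood over 1-based class indices (internal fast path)
.ll_idx <- function(beta, x, y) {
  eta <- .logits(beta, x)
  sum(eta[cbind(seq_along(y), y)] - .row_lse(eta))
}

# Analytic gradient (length 8, contrast-major: type2a terms then type2b
# terms) and Hessian (8x8) of the log-likelihood.
.mlr_grad_hess <- function(beta, x, y) {
  z <- cbind(1, x)
  p <- .softmax_probs(beta, x)
  g <- numeric(8L)
  for (c in 1:2) {
    ind <- as.numeric(y == c + 1L)
    g[(c - 1L) * 4L + 1:4] <- crossprod(z, ind - p[, c + 1L])
  }
  h <- matrix(0, 8L, 8L)
  for (c in 1:2) {
    for (d in 1:2) {
      w <- p[, c + 1L] * ((c == d) - p[, d + 1L])
      h[(c - 1L) * 4L + 1:4, (d - 1L) * 4L + 1:4] <- -crossprod(z, z * w)
    }
  }
  list(gradient = g, hessian = h)
}

#' Fit the cell-type classifier by maximum likelihood
#'
#' Newton-Raphson maximization of the multinomial log-likelihood, started at
#' the zero coefficient matrix (the likelihood is concave, so the optimum is
#' unique whenever the classes are not separable) with step halving. The fit
#' is fully deterministic. If any coefficient magnitude exceeds 50 during
#' iteration, probable class separation is reported rather than returning
#' quasi-infinite coefficients.
#'
#' @param x feature matrix (n x 3); at least 3 cells.
#' @param labels class labels with at least 2 distinct values; the reference
#'   class `type1` must be present.
#' @param tol convergence tolerance on the gradient max-norm (default 1e-8).
#' @param max_iter maximum Newton iterations.
#' @param genotype optional genotype tag stored on the model.
#' @param standardization optional `standardization_params` stored on the
#'   model so raw cells can be classified later.
#' @return an `mlr_model`: `beta` (2x4), `se` (2x4 asymptotic standard
#'   errors), `genotype`, `standardization`, and `fit_meta` (log-likelihood,
#'   iterations, converged flag, separation flag, n).
#' @export
fit_mlr <- function(x, labels, tol = 1e-8, max_iter = 200L,
                    genotype = NA_character_, standardization = NULL) {
  x <- .as_feature_matrix(x)
  y <- .as_label_index(labels)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 cells to fit", call. = FALSE)
  if (n != length(y)) stop("features and labels differ in length", call. = FALSE)
  if (length(unique(y)) < 2L) stop("labels contain a single class", call. = FALSE)
  if (!1L %in% y) stop("reference class type1 absent from labels", call. = FALSE)

  beta <- matrix(0, 2L, 4L)
  ll <- .ll_idx(beta, x, y)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gh <- .mlr_grad_hess(beta, x, y)
    if (max(abs(gh$gradient)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(gh$hessian, gh$gradient),
                     error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(gh$hessian - diag(1e-8, 8L), gh$gradient)
    }
    # Newton ascent: beta <- beta - H^{-1} g, with halving if ll drops
    scale <- 1
    repeat {
      cand <- beta - matrix(step * scale, 2L, 4L, byrow = TRUE)
      cand_ll <- .ll_idx(cand, x, y)
      if (cand_ll >= ll - 1e-12 || scale < 1e-8) break
      scale <- scale / 2
    }
    beta <- cand
    ll <- cand_ll
    if (max(abs(beta)) > 50) { separation <- TRUE; break }
  }
  if (separation) {
    warning("probable class separation: coefficient magnitude exceeded 50; ",
            "maximum-likelihood estimates do not exist (likelihood unbounded)",
            call. = FALSE)
  } else if (!converged) {
    warning("fit_mlr did not reach gradient tolerance ", tol, " in ",
            max_iter, " iterations", call. = FALSE)
  }
  gh <- .mlr_grad_hess(beta, x, y)
  se <- tryCatch({
    v <- solve(-gh$hessian)
    matrix(sqrt(pmax(diag(v), 0)), 2L, 4L, byrow = TRUE,
           dimnames = list(.contrast_names, .term_names))
  }, error = function(e) matrix(NA_real_, 2L, 4L))
  structure(
    list(beta = .as_beta(beta), se = se, genotype = genotype,
         standardization = standardization,
         fit_meta = list(log_likelihood = ll, iterations = iter,
                         converged = converged, separation = separation,
                         n = n, tol = tol)),
    class = "mlr_model"
  )
}

#' Construct a model object from known coefficients
#'
#' @param beta 2x4 coefficient matrix.
#' @param genotype `"WT"` or `"KO"` (or `NA`).
#' @param standardization optional `standardization_params`; required before
#'   the model can classify raw cell records.
#' @return an `mlr_model`.
#' @export
mlr_model <- function(beta, genotype = NA_character_, standardization = NULL) {
  structure(
    list(beta = .as_beta(beta), se = NULL, genotype = genotype,
         standardization = standardization,
         fit_meta = list(log_likelihood = NA_real_, iterations = 0L,
                         converged = NA, separation = FALSE, n = NA_integer_)),
    class = "mlr_model"
  )
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("Multinomial logistic cell-type model",
      if (!is.na(x$genotype)) paste0("(", x$genotype, ")"), "\n")
  print(round(x$beta, 4))
  if (!is.null(x$standardization)) {
    cat("standardization: fitted on", x$standardization$n_cells, "cells (",
        x$standardization$sd_denom, "sd )\n")
  } else {
    cat("standardization: external - must be supplied before classifying raw cells\n")
  }
  invisible(x)
}

#' Published per-genotype coefficient fixtures
#'
#' Returns the reported coefficient matrix for the wild-type or knockout
#' classifier. The source publication prints only the coefficients, not the
#' feature means and scales, so the returned model carries no
#' standardization: attach one (e.g. fitted on your own cohort) before
#' classifying raw records; prediction from already-standardized features
#' works directly.
#'
#' @param genotype `"WT"` or `"KO"`.
#' @return an `mlr_model` with the printed `beta` and no standardization.
#' @export
published_model <- function(genotype = c("WT", "KO")) {
  genotype <- match.arg(genotype)
  beta <- switch(genotype,
    WT = rbind(c(-0.343, -1.067, -1.317, 1.681),
               c(-3.074, -2.746, 0.782, 1.359)),
    KO = rbind(c(0.567, -1.373, -0.051, 0.302),
               c(-5.353, -6.935, -1.626, 5.549))
  )
  mlr_model(beta, genotype = genotype)
}

#' Class probabilities for standardized feature vectors
#'
#' Evaluates the softmax over logits `(0, b1'z, b2'z)` with `z = (1, x)`,
#' assigns each cell to the class of highest probability, and flags ties
#' (top two probabilities within 1e-12; ties break toward the lower class
#' index, i.e. toward type1).
#'
#' @param model an `mlr_model` (or bare 2x4 beta matrix).
#' @param x a length-3 feature vector or an n x 3 matrix.
#' @return a `class_posterior` list: `probabilities` (n x 3 matrix, rows sum
#'   to 1), `assigned` (factor over the three types), `tie` (logical).
#' @export
predict_proba <- function(model, x) {
  beta <- if (inherits(model, "mlr_model")) model$beta else .as_beta(model)
  x <- .as_feature_matrix(x)
  p <- .softmax_probs(beta, x)
  ord_assign <- function(row) {
    top <- max(row)
    which(row >= top - 1e-12)[1L]  # lower index wins ties
  }
  idx <- apply(p, 1L, ord_assign)
  tie <- apply(p, 1L, function(row) {
    s <- sort(row, decreasing = TRUE)
    (s[1L] - s[2L]) < 1e-12
  })
  structure(
    list(probabilities = p,
         assigned = factor(.cell_types[idx], levels = .cell_types),
         tie = tie),
    class = "class_posterior"
  )
}

#' Classify raw cell records with a fitted model
#'
#' Standardizes each record with the model's attached standardization
#' parameters and applies [predict_proba()]. Errors if the model has no
#' standardization (the published coefficient fixtures ship without one) or
#' if the genotype does not match.
#'
#' @param model an `mlr_model` with `standardization` attached.
#' @param records a `cell_records` table (normally QC-passing cells of the
#'   model's genotype).
#' @param check_genotype passed to [apply_standardization()].
#' @return list with `assignments` (data.frame: cell_id, genotype, the three
#'   class probabilities, assigned, tie) and `counts` (named integer vector
#'   over the three types).
#' @export
classify_cells <- function(model, records, check_genotype = TRUE) {
  stopifnot(inherits(model, "mlr_model"))
  if (is.null(model$standardization)) {
    stop("model has no standardization parameters attached; ",
         "supply them before classifying raw cell records", call. = FALSE)
  }
  records <- validate_cell_records(records)
  if (nrow(records) == 0L) {
    counts <- stats::setNames(integer(3L), .cell_types)
    return(list(assignments = data.frame(), counts = counts))
  }
  x <- apply_standardization(model$standardization, records,
                             check_genotype = check_genotype)
  post <- predict_proba(model, x)
  assignments <- data.frame(
    cell_id = records$cell_id,
    genotype = records$genotype,
    p_type1 = post$probabilities[, 1L],
    p_type2a = post$probabilities[, 2L],
    p_type2b = post$probabilities[, 3L],
    assigned = as.character(post$assigned),
    tie = post$tie,
    stringsAsFactors = FALSE
  )
  counts <- stats::setNames(
    as.integer(table(factor(assignments$assigned, levels = .cell_types))),
    .cell_types
  )
  list(assignments = assignments, counts = counts)
}

#' Resubstitution accuracy on marker-labeled cells
#'
#' Fraction of cells whose assigned class equals the marker-determined
#' `known_type`. Every record must carry a label.
#'
#' @param model an `mlr_model` with standardization.
#' @param records labeled `cell_records`.
#' @param check_genotype passed through to [classify_cells()].
#' @return fraction in `[0, 1]`.
#' @export
training_accuracy <- function(model, records, check_genotype = TRUE) {
  records <- validate_cell_records(records)
  if (nrow(records) == 0L || anyNA(records$known_type)) {
    stop("training_accuracy needs records that all carry known_type", call. = FALSE)
  }
  res <- classify_cells(model, records, check_genotype = check_genotype)
  mean(res$assignments$assigned == records$known_type)
}

#' Class-probability profile along one feature
#'
#' Sweeps one standardized feature over a grid while holding the other two
#' fixed, returning the three class probabilities at each grid point — the
#' numerical content of the per-feature probability heatmaps.
#'
#' @param model an `mlr_model` (standardized-feature space).
#' @param feature_index 1 (log Cm), 2 (log Rm) or 3 (Vm).
#' @param grid finite numeric vector of standardized feature values.
#' @param others_at length-2 vector of fixed values for the other two
#'   features, in increasing feature order (default both 0, the feature
#'   means).
#' @return matrix with one row per grid point (rownames = grid values) and
#'   columns `type1, type2a, type2b`; each row sums to 1.
#' @export
probability_profile <- function(model, feature_index, grid, others_at = c(0, 0)) {
  stopifnot(feature_index %in% 1:3, length(others_at) == 2L)
  grid <- as.numeric(grid)
  if (length(grid) == 0L || !all(is.finite(grid))) {
    stop("grid must be non-empty and finite", call. = FALSE)
  }
  x <- matrix(NA_real_, length(grid), 3L)
  x[, feature_index] <- grid
  x[, setdiff(1:3, feature_index)] <- matrix(others_at, length(grid), 2L,
                                             byrow = TRUE)
  p <- predict_proba(model, x)$probabilities
  rownames(p) <- format(grid)
  p
}

#' Write a model to JSON
#'
#' Serializes beta, standardization, genotype and fit metadata with stable
#' field names and a format version tag.
#'
#' @param model an `mlr_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mlr_model <- function(model, path) {
  stopifnot(inherits(model, "mlr_model"))
  doc <- list(
    format = "sgzephys-mlr-model",
    version = 1L,
    genotype = model$genotype,
    beta = apply(model$beta, 1L, as.list, simplify = FALSE),
    standardization = if (is.null(model$standardization)) NULL else
      standardization_as_list(model$standardization),
    fit_meta = model$fit_meta
  )
  names(doc$beta) <- .contrast_names
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model from JSON
#' @param path path written by [write_mlr_model()].
#' @return an `mlr_model`.
#' @export
read_mlr_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "sgzephys-mlr-model")) {
    stop("not an sgzephys model file: ", path, call. = FALSE)
  }
  beta <- rbind(unlist(doc$beta$type2a), unlist(doc$beta$type2b))
  std <- if (is.null(doc$standardization)) NULL else
    standardization_from_list(doc$standardization)
  m <- mlr_model(beta, genotype = doc$genotype, standardization = std)
  if (!is.null(doc$fit_meta)) m$fit_meta <- doc$fit_meta
  m
}

#' Fit both genotype models and classify a cohort
#'
#' The full classification analysis on one cell table: per genotype,
#' standardization is fitted on all QC-passing cells, the classifier is
#' fitted by maximum likelihood on the marker-labeled subset, every cell is
#' assigned to its most probable type, and resubstitution accuracy is
#' evaluated on the labeled cells. Both sd-denominator variants of the
#' standardization can be run for sensitivity.
#'
#' @param records a `cell_records` table (both genotypes allowed).
#' @param sd_denom standardization variants to run (default both).
#' @param qc a [qc_config()] applied first, or `NULL` to skip filtering.
#' @return nested list: per variant, per genotype — `model`, `counts`,
#'   `accuracy`, `n_labeled`, `n_cells`.
#' @export
reproduce_published_fit <- function(records, sd_denom = c("n-1", "n"),
                                    qc = qc_config()) {
  records <- validate_cell_records(records)
  if (!is.null(qc)) records <- qc_filter(records, qc)$kept
  out <- list()
  for (sdv in sd_denom) {
    per_geno <- list()
    for (g in intersect(.genotypes, unique(records$genotype))) {
      cells <- records[records$genotype == g, , drop = FALSE]
      std <- fit_standardization(cells, sd_denom = sdv)
      labeled <- cells[!is.na(cells$known_type), , drop = FALSE]
      x_lab <- apply_standardization(std, labeled)
      model <- fit_mlr(x_lab, labeled$known_type, genotype = g,
                       standardization = std)
      cls <- classify_cells(model, cells)
      per_geno[[g]] <- list(
        model = model,
        counts = cls$counts,
        accuracy = training_accuracy(model, labeled),
        n_labeled = nrow(labeled),
        n_cells = nrow(cells)
      )
    }
    out[[sdv]] <- per_geno
  }
  out
}
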