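# End-to-end wiring: simulate (or load) -> QC -> standardize/fit -> classify
# -> group comparisons, with provenance. The numbered scripts under
# analysis/ drive these stages individually; run_pipeline() executes them as
# one deterministic unit.

#' Default pipeline configuration
#'
#' @param seed master RNG seed for the synthetic cohort.
#' @param n_cells cells per genotype to simulate.
#' @param qc list of [qc_config()] arguments.
#' @param sd_denom standardization variant for the fitted models.
#' @param out_dir optional directory; when set, stage outputs (cell table,
#'   model JSONs, assignment table, report) are written there.
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed = 1L, n_cells = 200L, qc = list(),
                       sd_denom = "n-1", out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              qc = do.call(qc_config, qc), sd_denom = sd_denom,
              out_dir = out_dir)
  if (!cfg$sd_denom %in% c("n-1", "n")) stop("sd_denom must be 'n-1' or 'n'", call. = FALSE)
  if (cfg$n_cells < 10L) stop("n_cells must be at least 10", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys: `seed`, `n_cells`, `qc` (max_series_resistance,
#' min_holding_current, combine_rule), `sd_denom`, `out_dir`. Unknown keys
#' are rejected.
#'
#' @param path YAML config path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "n_cells", "qc", "sd_denom", "out_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Run the full classification pipeline on a synthetic cohort
#'
#' Generates a two-genotype cohort, applies recording QC, fits per-genotype
#' standardization (on all QC-passing cells) and the multinomial classifier
#' (on the marker-labeled subset), classifies every cell, and compares
#' resting membrane potential across genotype-by-assigned-type groups
#' (two-way type II ANOVA plus Sidak-adjusted pairwise Welch tests within
#' each assigned type). Fully deterministic given the config.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `provenance` (seed, config hash, package
#'   version), `qc` (kept/excluded counts), per-genotype `models`, `counts`,
#'   `accuracy`, the `assignments` table, and `vm_comparison` (ANOVA table
#'   plus per-type genotype contrasts).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sim <- generate_cells(generator_config(seed = config$seed,
                                         n_cells = config$n_cells))
  qc <- qc_filter(sim$records, config$qc)
  kept <- qc$kept

  models <- list(); counts <- list(); accuracy <- list()
  assignments <- list()
  for (g in c("WT", "KO")) {
    cells <- kept[kept$genotype == g, , drop = FALSE]
    std <- fit_standardization(cells, sd_denom = config$sd_denom)
    labeled <- cells[!is.na(cells$known_type), , drop = FALSE]
    x_lab <- apply_standardization(std, labeled)
    model <- fit_mlr(x_lab, labeled$known_type, genotype = g,
                     standardization = std)
    cls <- classify_cells(model, cells)
    models[[g]] <- model
    counts[[g]] <- cls$counts
    accuracy[[g]] <- training_accuracy(model, labeled)
    assignments[[g]] <- cls$assignments
  }
  assign_tab <- do.call(rbind, c(assignments, make.row.names = FALSE))

  pred <- merge(kept[, c("cell_id", "vm")], assign_tab, by = "cell_id")
  anova_tab <- two_way_anova(pred$vm, pred$genotype, pred$assigned)
  per_type <- lapply(stats::setNames(.cell_types, .cell_types), function(ty) {
    sub <- pred[pred$assigned == ty, , drop = FALSE]
    if (length(unique(sub$genotype)) < 2L || nrow(sub) < 4L) return(NULL)
    tt <- stats::t.test(vm ~ genotype, data = sub)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_vm = tapply(sub$vm, sub$genotype, mean))
  })
  raw_p <- vapply(per_type, function(x) if (is.null(x)) NA_real_ else x$p_value,
                  numeric(1))
  adj <- sidak_adjust(raw_p[!is.na(raw_p)], m = sum(!is.na(raw_p)))
  j <- 1L
  for (ty in names(per_type)) {
    if (!is.null(per_type[[ty]])) {
      per_type[[ty]]$p_adjusted <- adj[j]
      j <- j + 1L
    }
  }

  report <- list(
    provenance = list(seed = config$seed,
                      config_hash = .hash_config(config),
                      package_version = as.character(utils::packageVersion("sgzephys"))),
    qc = list(n_input = nrow(sim$records), n_kept = nrow(kept),
              n_excluded = nrow(qc$excluded)),
    models = models, counts = counts, accuracy = accuracy,
    assignments = assign_tab,
    vm_comparison = list(anova = anova_tab, per_type = per_type)
  )
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cell_table(kept, file.path(config$out_dir, "cells_qc_passed.csv"))
    for (g in names(models)) {
      write_mlr_model(models[[g]], file.path(config$out_dir,
                                             paste0("model_", g, ".json")))
    }
    utils::write.csv(assign_tab,
                     file.path(config$out_dir, "assignments.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(provenance = report$provenance, qc = report$qc,
           counts = counts, accuracy = accuracy),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  report
}

# Stable md5 hash of the configuration (via its deparsed form).
.hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}
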