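# Seeded generators for every pipeline input. All generators are pure
# functions of (config, seed). The archetype numbers are invented plausible
# values for testing the pipeline — they are NOT measurements from any
# publication, and nothing downstream asserts them against reported data.

#' Default biophysical archetypes per type and genotype
#'
#' Vm is normal (mean/sd in mV); Rm and Cm are log-normal (meanlog/sdlog of
#' MOhm and pF). The structure encodes the qualitative progression the
#' classifier exploits: type 1 cells hyperpolarized with low resistance and
#' high capacitance (extensive gap-junction coupling), type 2b cells
#' depolarized with high resistance and low capacitance (electrically
#' isolated), type 2a intermediate; knockout type 2b cells are further
#' depolarized. Values are invented plausible defaults, configurable.
#'
#' @return data.frame with one row per (type, genotype).
#' @export
default_archetypes <- function() {
  base <- data.frame(
    type = rep(c("type1", "type2a", "type2b"), each = 2L),
    genotype = rep(c("WT", "KO"), times = 3L),
    vm_mean = c(-85, -85, -80, -80, -75, -60),
    vm_sd = c(3, 3, 4, 4, 5, 8),
    rm_meanlog = log(c(50, 50, 500, 500, 2000, 2000)),
    rm_sdlog = rep(0.4, 6L),
    cm_meanlog = log(c(50, 50, 20, 20, 10, 10)),
    cm_sdlog = rep(0.35, 6L),
    stringsAsFactors = FALSE
  )
  base
}

#' Configuration for the synthetic cell-cohort generator
#'
#' @param seed integer RNG seed.
#' @param n_cells cells per genotype.
#' @param class_mixture probabilities over (type1, type2a, type2b); must sum
#'   to 1.
#' @param archetypes archetype table as from [default_archetypes()].
#' @param label_known_fraction probability that a cell carries a
#'   marker-determined label (emulating the minority of recorded cells whose
#'   identity survives post-hoc immunostaining).
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_cells = 200L,
                             class_mixture = c(0.6, 0.25, 0.15),
                             archetypes = default_archetypes(),
                             label_known_fraction = 0.3) {
  if (length(class_mixture) != 3L || any(class_mixture < 0) ||
      abs(sum(class_mixture) - 1) > 1e-9) {
    stop("class_mixture must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  need <- c("type", "genotype", "vm_mean", "vm_sd", "rm_meanlog", "rm_sdlog",
            "cm_meanlog", "cm_sdlog")
  if (!all(need %in% names(archetypes))) {
    stop("archetypes table lacks required columns", call. = FALSE)
  }
  if (any(archetypes$vm_sd <= 0) || any(archetypes$rm_sdlog <= 0) ||
      any(archetypes$cm_sdlog <= 0)) {
    stop("all archetype sds must be strictly positive", call. = FALSE)
  }
  if (label_known_fraction < 0 || label_known_fraction > 1) {
    stop("label_known_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_cells = as.integer(n_cells),
         class_mixture = class_mixture, archetypes = archetypes,
         label_known_fraction = label_known_fraction),
    class = "generator_config"
  )
}

#' Generate a synthetic cell cohort
#'
#' Draws `n_cells` cells per genotype: the type from `class_mixture`, then
#' (Vm, Rm, Cm) from the type-by-genotype archetype (Vm normal; Rm, Cm
#' log-normal). A `label_known_fraction` subset carries its true type as
#' `known_type`. QC fields are drawn to mostly pass the default thresholds
#' (series resistance log-normal around 8 MOhm, holding current normal
#' around -30 pA), so occasional cells fail QC as in real cohorts.
#' Deterministic for a fixed config.
#'
#' @param config a [generator_config()].
#' @return list with `records` (a `cell_records` table) and `truth`
#'   (data.frame cell_id, true_type).
#' @export
generate_cells <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  all_rec <- list()
  truth <- list()
  for (g in c("WT", "KO")) {
    n <- config$n_cells
    types <- sample(.cell_types, n, replace = TRUE, prob = config$class_mixture)
    arch <- config$archetypes
    key <- match(paste(types, g), paste(arch$type, arch$genotype))
    if (anyNA(key)) stop("archetype table lacks a (type, genotype) row", call. = FALSE)
    vm <- stats::rnorm(n, arch$vm_mean[key], arch$vm_sd[key])
    rm_ <- stats::rlnorm(n, arch$rm_meanlog[key], arch$rm_sdlog[key])
    cm <- stats::rlnorm(n, arch$cm_meanlog[key], arch$cm_sdlog[key])
    known <- stats::runif(n) < config$label_known_fraction
    sr <- stats::rlnorm(n, log(8), 0.45)
    hc <- stats::rnorm(n, -30, 25)
    ids <- sprintf("%s-%04d", g, seq_len(n))
    all_rec[[g]] <- data.frame(
      cell_id = ids, genotype = g, vm = vm, rm = rm_, cm = cm,
      known_type = ifelse(known, types, NA_character_),
      series_resistance = sr, holding_current = hc,
      reporter = "Fezf2-GFP", stringsAsFactors = FALSE
    )
    truth[[g]] <- data.frame(cell_id = ids, true_type = types,
                             stringsAsFactors = FALSE)
  }
  list(records = validate_cell_records(do.call(rbind, c(all_rec, make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Simulate labeled cells from a classifier model
#'
#' Draws standardized feature vectors from the standard trivariate normal
#' and samples each cell's label from the model's class probabilities at its
#' features — the generative counterpart of the classifier, used for
#' parameter-recovery checks on known coefficients.
#'
#' @param model an `mlr_model` (or 2x4 beta matrix).
#' @param n number of cells.
#' @param seed integer RNG seed.
#' @return list with `x` (n x 3 standardized features) and `labels`
#'   (factor over the three types); empty for `n = 0`.
#' @export
generate_cells_from_model <- function(model, n, seed = 1L) {
  beta <- if (inherits(model, "mlr_model")) model$beta else .as_beta(model)
  n <- as.integer(n)
  if (n == 0L) {
    return(list(x = matrix(numeric(0), 0L, 3L),
                labels = factor(character(0), levels = .cell_types)))
  }
  set.seed(as.integer(seed))
  x <- matrix(stats::rnorm(3L * n), n, 3L)
  colnames(x) <- c("x1", "x2", "x3")
  p <- .softmax_probs(beta, x)
  u <- stats::runif(n)
  cum <- cbind(p[, 1L], p[, 1L] + p[, 2L], 1)
  idx <- 1L + (u > cum[, 1L]) + (u > cum[, 2L])
  list(x = x, labels = factor(.cell_types[idx], levels = .cell_types))
}

#' Generate synthetic voltage-step recordings
#'
#' Builds per-step current traces for three cell archetypes: `passive`
#' (ohmic leak plus a decaying capacitive transient at step onset),
#' `rectifier` (adds a Boltzmann-activated outward potassium conductance
#' with first-order activation kinetics), and `rectifier_with_na` (further
#' adds a brief inactivating inward current at steps more positive than
#' -30 mV, emulating a nascent sodium current). Gaussian noise of sd
#' `noise_sd_pa` is added throughout.
#'
#' @param archetype one of `"passive"`, `"rectifier"`, `"rectifier_with_na"`.
#' @param protocol a [step_protocol()].
#' @param rest_mv resting (reversal of the leak) potential, mV.
#' @param r_leak_mohm leak resistance, MOhm.
#' @param cm_pf membrane capacitance, pF (sets the capacitive transient).
#' @param g_k_ns maximal Boltzmann conductance, nS.
#' @param vhalf_mv,slope_mv Boltzmann half-activation and slope, mV.
#' @param ek_mv potassium reversal potential, mV.
#' @param na_amp_pa peak amplitude of the inward transient, pA.
#' @param noise_sd_pa Gaussian noise sd, pA.
#' @param seed integer RNG seed (noise only).
#' @return a `voltage_step_recording` (see [voltage_step_recording()]).
#' @export
generate_voltage_steps <- function(archetype = c("passive", "rectifier",
                                                 "rectifier_with_na"),
                                   protocol = step_protocol(),
                                   rest_mv = -80, r_leak_mohm = 100,
                                   cm_pf = 20, g_k_ns = 5, vhalf_mv = -30,
                                   slope_mv = 10, ek_mv = -90,
                                   na_amp_pa = 400, noise_sd_pa = 0,
                                   seed = 1L) {
  archetype <- match.arg(archetype)
  stopifnot(inherits(protocol, "step_protocol"))
  set.seed(as.integer(seed))
  t_ms <- protocol$time_ms
  in_step <- t_ms >= protocol$onset_ms & t_ms < protocol$offset_ms
  tau_m <- r_leak_mohm * cm_pf / 1000  # ms (MOhm * pF = us)
  traces <- sapply(protocol$levels, function(v_step) {
    i <- numeric(length(t_ms))
    v_hold <- protocol$holding
    # leak: pA = mV / MOhm * 1000
    i[!in_step] <- (v_hold - rest_mv) / r_leak_mohm * 1000
    i[in_step] <- (v_step - rest_mv) / r_leak_mohm * 1000
    # capacitive charging transient at onset (and decay at offset)
    ts <- t_ms[in_step] - protocol$onset_ms
    i[in_step] <- i[in_step] +
      (v_step - v_hold) / r_leak_mohm * 1000 * exp(-ts / max(tau_m, 0.2))
    if (archetype %in% c("rectifier", "rectifier_with_na")) {
      g <- g_k_ns / (1 + exp(-(v_step - vhalf_mv) / slope_mv))
      act <- 1 - exp(-ts / 5)  # 5 ms activation
      i[in_step] <- i[in_step] + g * (v_step - ek_mv) * act
    }
    if (archetype == "rectifier_with_na" && v_step > -30) {
      shape <- (1 - exp(-ts / 0.4)) * exp(-ts / 1.5)
      shape <- shape / max(shape)
      i[in_step] <- i[in_step] - na_amp_pa * shape
    }
    if (noise_sd_pa > 0) i <- i + stats::rnorm(length(i), 0, noise_sd_pa)
    i
  })
  voltage_step_recording(protocol, traces)
}

#' Generate a synthetic clone field
#'
#' Places `n_clones` clone centers uniformly in a 3D extent subject to a
#' minimum inter-center distance, then scatters each clone's members
#' uniformly within a ball of radius `scatter_um` around its center (a hard
#' scatter bound, so geometric recovery guarantees hold). When the
#' separation is smaller than twice the scatter bound, ground truth may not
#' be recoverable and `hard = TRUE` must be passed.
#'
#' @param n_clones number of clones.
#' @param size_distribution function(n) returning n integer clone sizes
#'   (default: 1 + rpois(n, 3)).
#' @param extent_um length-3 upper corner of the axis-aligned field, µm.
#' @param scatter_um scatter-ball radius around each center, µm.
#' @param min_separation_um minimum distance between clone centers, µm.
#' @param group group label attached to every cell.
#' @param hard allow configurations whose ground truth is not guaranteed
#'   recoverable.
#' @param max_tries center-placement retries before giving up.
#' @param seed integer RNG seed.
#' @return list with `map` (a `clone_map` data.frame: cell_id, x_um, y_um,
#'   z_um, group) and `truth` (cell_id, true_clone).
#' @export
generate_clone_field <- function(n_clones, size_distribution = NULL,
                                 extent_um = c(1000, 1000, 300),
                                 scatter_um = 20, min_separation_um = 300,
                                 group = "WT", hard = FALSE,
                                 max_tries = 2000L, seed = 1L) {
  if (is.null(size_distribution)) {
    size_distribution <- function(n) 1L + stats::rpois(n, 3)
  }
  if (!hard && min_separation_um <= 2 * scatter_um) {
    stop("min_separation_um must exceed 2 * scatter_um for recoverable ",
         "ground truth; pass hard = TRUE to generate anyway", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (n_clones == 0L) {
    map <- data.frame(cell_id = character(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      group = character(0), stringsAsFactors = FALSE)
    return(list(map = map,
                truth = data.frame(cell_id = character(0),
                                   true_clone = integer(0))))
  }
  centers <- matrix(NA_real_, 0L, 3L)
  tries <- 0L
  while (nrow(centers) < n_clones) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n_clones, " clone centers with separation ",
           min_separation_um, " µm in the given extent", call. = FALSE)
    }
    cand <- stats::runif(3L, 0, extent_um)
    if (nrow(centers) == 0L ||
        all(sqrt(colSums((t(centers) - cand)^2)) >= min_separation_um)) {
      centers <- rbind(centers, cand)
    }
  }
  sizes <- pmax(1L, as.integer(size_distribution(n_clones)))
  rows <- list()
  truth <- list()
  for (k in seq_len(n_clones)) {
    m <- sizes[k]
    # uniform in a ball of radius scatter_um
    dir <- matrix(stats::rnorm(3L * m), m, 3L)
    dir <- dir / sqrt(rowSums(dir^2))
    r <- scatter_um * stats::runif(m)^(1 / 3)
    pts <- sweep(dir * r, 2L, centers[k, ], "+")
    ids <- sprintf("%s-c%03d-%03d", group, k, seq_len(m))
    rows[[k]] <- data.frame(cell_id = ids, x_um = pts[, 1L], y_um = pts[, 2L],
                            z_um = pts[, 3L], group = group,
                            stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(cell_id = ids, true_clone = k,
                             stringsAsFactors = FALSE)
  }
  list(map = do.call(rbind, c(rows, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Generate a synthetic per-cell fluorescence intensity table
#'
#' Log-normal phospho-signal intensity `f1`, marker intensity `f2` and
#' measured cell `area_nm2`, as consumed by [normalize_phospho()].
#'
#' @param n_cells rows to generate.
#' @param f1_meanlog,f1_sdlog log-normal parameters of the phospho signal.
#' @param f2_meanlog,f2_sdlog log-normal parameters of the marker signal.
#' @param area_meanlog,area_sdlog log-normal parameters of the area (nm^2).
#' @param group group label column.
#' @param seed integer RNG seed.
#' @return data.frame (cell_id, f1, f2, area_nm2, group).
#' @export
generate_intensity_table <- function(n_cells, f1_meanlog = log(100),
                                     f1_sdlog = 0.5, f2_meanlog = log(50),
                                     f2_sdlog = 0.3,
                                     area_meanlog = log(5e4),
                                     area_sdlog = 0.2, group = "WT",
                                     seed = 1L) {
  set.seed(as.integer(seed))
  data.frame(
    cell_id = sprintf("%s-i%04d", group, seq_len(n_cells)),
    f1 = stats::rlnorm(n_cells, f1_meanlog, f1_sdlog),
    f2 = stats::rlnorm(n_cells, f2_meanlog, f2_sdlog),
    area_nm2 = stats::rlnorm(n_cells, area_meanlog, area_sdlog),
    group = group,
    stringsAsFactors = FALSE
  )
}
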