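# Clone calling from 3D coordinates of lineage-labeled cells and clone-size
# distribution comparison.

#' Validate a clone map (labeled-cell coordinate table)
#'
#' @param map data.frame with columns cell_id, x_um, y_um, z_um and
#'   optionally group; coordinates finite, ids unique.
#' @return the validated map, classed `clone_map`.
#' @export
clone_map <- function(map) {
  stopifnot(is.data.frame(map))
  need <- c("cell_id", "x_um", "y_um", "z_um")
  missing <- setdiff(need, names(map))
  if (length(missing) > 0L) {
    stop("clone map missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(map$cell_id)) stop("duplicated cell_id values", call. = FALSE)
  coords <- as.matrix(map[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (is.null(map$group)) map$group <- rep("all", nrow(map))
  class(map) <- unique(c("clone_map", class(map)))
  map
}

# Greedy fixed-radius covering within one group of cells.
.call_clones_one <- function(map, radius, dims) {
  n <- nrow(map)
  coords <- as.matrix(map[, c("x_um", "y_um", "z_um")[seq_len(dims)]])
  d <- as.matrix(stats::dist(coords))
  unassigned <- rep(TRUE, n)
  assign <- integer(n)
  centers <- list()
  clone_id <- 0L
  while (any(unassigned)) {
    cover <- colSums(d[unassigned, , drop = FALSE] <= radius)
    cover[!unassigned] <- -1L
    best <- max(cover)
    cand <- which(cover == best)
    seed <- cand[order(map$cell_id[cand])[1L]]   # tie -> smallest cell_id
    members <- which(unassigned & d[seed, ] <= radius)
    clone_id <- clone_id + 1L
    assign[members] <- clone_id
    unassigned[members] <- FALSE
    centers[[clone_id]] <- coords[seed, ]
  }
  list(assign = assign, centers = centers)
}

#' Call clones from labeled-cell coordinates
#'
#' Partitions the cells of each group into clones with a fixed-radius rule:
#' a clone is the set of cells within `radius_um` of its center. Centers
#' are found greedily — repeatedly seed a clone at the unassigned cell whose
#' radius-ball covers the most unassigned cells (ties broken toward the
#' lexicographically smallest cell id), assign that ball's unassigned cells
#' to the clone, and continue until every cell belongs to exactly one
#' clone. The greedy max-coverage seeding is this package's deterministic
#' operationalization of "cells within a fixed radius of the clone
#' center"; on well-separated fields it recovers the generating clones
#' exactly.
#'
#' @param map a [clone_map()] (or compatible data.frame).
#' @param radius_um clone radius, µm (default 100).
#' @param dims 3 for Euclidean distance in 3D (default), 2 to ignore z (a
#'   projection mode).
#' @return list: `cells` (map plus `clone_id`), `clones` (data.frame
#'   clone_id, group, center_x/y/z_um, size).
#' @export
call_clones <- function(map, radius_um = 100, dims = 3L) {
  map <- clone_map(as.data.frame(map))
  if (radius_um <= 0) stop("radius must be positive", call. = FALSE)
  stopifnot(dims %in% c(2L, 3L))
  if (nrow(map) == 0L) {
    return(list(cells = cbind(map, clone_id = character(0)),
                clones = data.frame(clone_id = character(0),
                                    group = character(0),
                                    center_x_um = numeric(0),
                                    center_y_um = numeric(0),
                                    center_z_um = numeric(0),
                                    size = integer(0))))
  }
  out_cells <- list()
  out_clones <- list()
  for (g in unique(map$group)) {
    sub <- map[map$group == g, , drop = FALSE]
    res <- .call_clones_one(sub, radius_um, dims)
    ids <- sprintf("%s-%03d", g, res$assign)
    sub$clone_id <- ids
    out_cells[[g]] <- sub
    ctr <- do.call(rbind, res$centers)
    sizes <- as.integer(table(res$assign)[as.character(seq_along(res$centers))])
    out_clones[[g]] <- data.frame(
      clone_id = sprintf("%s-%03d", g, seq_along(res$centers)),
      group = g,
      center_x_um = ctr[, 1L],
      center_y_um = ctr[, 2L],
      center_z_um = if (dims == 3L) ctr[, 3L] else NA_real_,
      size = sizes,
      stringsAsFactors = FALSE
    )
  }
  list(cells = do.call(rbind, c(out_cells, make.row.names = FALSE)),
       clones = do.call(rbind, c(out_clones, make.row.names = FALSE)))
}

#' Empirical cumulative distribution of clone sizes
#'
#' @param sizes integer clone sizes (>= 1 of them).
#' @return data.frame (size, ecdf): right-continuous step values at each
#'   distinct size.
#' @export
clone_size_ecdf <- function(sizes) {
  if (length(sizes) == 0L) stop("no clones supplied", call. = FALSE)
  s <- sort(unique(sizes))
  data.frame(size = s, ecdf = stats::ecdf(sizes)(s))
}

#' Compare clone-size distributions between two groups
#'
#' Reports the two-sample Kolmogorov-Smirnov statistic `D` (the supremum
#' gap between the two empirical CDFs) with its asymptotic p-value, and a
#' two-sample t-test on the sizes (Welch by default; the pooled-variance
#' variant is available since reports rarely state which was used).
#'
#' @param sizes_a,sizes_b clone sizes of the two groups (t component needs
#'   >= 2 per group).
#' @param t_variant `"welch"` (default) or `"pooled"`.
#' @return list: `ks` (statistic D, p_value), `t` (statistic, df, p_value),
#'   `n` (per-group counts).
#' @export
compare_clone_sizes <- function(sizes_a, sizes_b,
                                t_variant = c("welch", "pooled")) {
  t_variant <- match.arg(t_variant)
  if (length(sizes_a) == 0L || length(sizes_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(sizes_a, sizes_b, exact = FALSE))
  tt <- if (length(sizes_a) >= 2L && length(sizes_b) >= 2L) {
    stats::t.test(sizes_a, sizes_b, var.equal = (t_variant == "pooled"))
  } else NULL
  list(
    ks = list(method = "two-sample Kolmogorov-Smirnov (asymptotic)",
              statistic = unname(ks$statistic), p_value = ks$p.value),
    t = if (is.null(tt)) NULL else
      list(method = paste0("two-sample t-test (", t_variant, ")"),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value),
    n = c(a = length(sizes_a), b = length(sizes_b))
  )
}
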