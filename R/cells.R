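#' @keywords internal
"_PACKAGE"

# Canonical column names of the cell-table CSV interface. Units are fixed at
# the interface: mV, MOhm, pF.
.cell_table_columns <- c(
  cell_id           = "cell_id",
  genotype          = "genotype",
  vm                = "vm_mV",
  rm                = "rm_MOhm",
  cm                = "cm_pF",
  known_type        = "known_type",
  series_resistance = "series_resistance_MOhm",
  holding_current   = "holding_current_pA",
  reporter          = "reporter"
)

.genotypes <- c("WT", "KO")
.cell_types <- c("type1", "type2a", "type2b")

#' Build a table of per-cell biophysical records
#'
#' Assembles and validates the per-cell record table that every downstream
#' stage consumes: one row per recorded cell with its genotype, the three
#' biophysical features (resting membrane potential `vm` in mV, input
#' resistance `rm` in MOhm, membrane capacitance `cm` in pF), the optional
#' marker-determined cell type, and optional recording-quality fields.
#'
#' @param cell_id character vector of unique cell identifiers.
#' @param genotype `"WT"` or `"KO"` per cell.
#' @param vm resting membrane potential, mV (finite).
#' @param rm input resistance, MOhm (strictly positive).
#' @param cm membrane capacitance, pF (strictly positive).
#' @param known_type optional marker-identified type (`"type1"`, `"type2a"`,
#'   `"type2b"`); `NA` for cells whose identity was not recovered.
#' @param series_resistance optional series resistance, MOhm.
#' @param holding_current optional holding current at -70 mV, pA.
#' @param reporter optional reporter-line annotation.
#' @return a `data.frame` of class `cell_records`.
#' @export
cell_records <- function(cell_id, genotype, vm, rm, cm,
                         known_type = NA_character_,
                         series_resistance = NA_real_,
                         holding_current = NA_real_,
                         reporter = NA_character_) {
  df <- data.frame(
    cell_id = as.character(cell_id),
    genotype = as.character(genotype),
    vm = as.numeric(vm),
    rm = as.numeric(rm),
    cm = as.numeric(cm),
    known_type = rep_len(as.character(known_type), length(cell_id)),
    series_resistance = rep_len(as.numeric(series_resistance), length(cell_id)),
    holding_current = rep_len(as.numeric(holding_current), length(cell_id)),
    reporter = rep_len(as.character(reporter), length(cell_id)),
    stringsAsFactors = FALSE
  )
  validate_cell_records(df)
}

#' Validate a cell-record table
#'
#' Checks the invariants of the record table: unique ids, recognised
#' genotypes and type labels, finite `vm`, and strictly positive `rm`, `cm`.
#'
#' @param df a data.frame with the `cell_records` columns.
#' @return the validated table, classed `cell_records`.
#' @export
validate_cell_records <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("cell_id", "genotype", "vm", "rm", "cm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$cell_id)) {
    stop("duplicated cell_id values", call. = FALSE)
  }
  if (!all(df$genotype %in% .genotypes)) {
    bad <- unique(df$genotype[!df$genotype %in% .genotypes])
    stop("unknown genotype value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  kt <- df$known_type
  if (!is.null(kt) && !all(is.na(kt) | kt %in% .cell_types)) {
    stop("known_type must be one of ", paste(.cell_types, collapse = ", "),
         " or NA", call. = FALSE)
  }
  if (!all(is.finite(df$vm))) stop("vm must be finite for every cell", call. = FALSE)
  if (!all(is.finite(df$rm) & df$rm > 0)) stop("rm must be positive and finite", call. = FALSE)
  if (!all(is.finite(df$cm) & df$cm > 0)) stop("cm must be positive and finite", call. = FALSE)
  for (opt in c("known_type", "series_resistance", "holding_current", "reporter")) {
    if (is.null(df[[opt]])) {
      df[[opt]] <- if (opt %in% c("series_resistance", "holding_current")) NA_real_ else NA_character_
    }
  }
  class(df) <- unique(c("cell_records", class(df)))
  df
}

#' Read a cell table from CSV
#'
#' Reads the delimited cell-table interface format (header row; columns
#' `cell_id, genotype, vm_mV, rm_MOhm, cm_pF` required, plus optional
#' `known_type, series_resistance_MOhm, holding_current_pA, reporter`).
#' Missing optional values are empty fields. A non-numeric value in a
#' required biophysics column is a row-level parse error naming the row;
#' absent required columns are schema errors naming the column. Unknown
#' types are stored as `NA`, never imputed.
#'
#' @param path path to the CSV file.
#' @param schema named character vector remapping internal field names
#'   (`cell_id`, `genotype`, `vm`, ...) to column names in the file;
#'   defaults to the canonical interface names.
#' @return a `cell_records` table.
#' @export
read_cell_table <- function(path, schema = .cell_table_columns) {
  cols <- .cell_table_columns
  cols[names(schema)] <- schema
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- cols[c("cell_id", "genotype", "vm", "rm", "cm")]
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(field, required_field) {
    col <- cols[[field]]
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    txt <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(txt))
    blank <- txt == "" | is.na(txt)
    bad <- which(is.na(out) & !blank)
    if (required_field && any(blank)) bad <- sort(union(bad, which(blank)))
    if (length(bad) > 0L && required_field) {
      stop("non-numeric value(s) in column '", col, "' at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out
  }
  parse_chr <- function(field) {
    col <- cols[[field]]
    if (!col %in% names(raw)) return(rep(NA_character_, nrow(raw)))
    txt <- trimws(raw[[col]])
    txt[txt == ""] <- NA_character_
    txt
  }
  df <- data.frame(
    cell_id = trimws(raw[[cols[["cell_id"]]]]),
    genotype = trimws(raw[[cols[["genotype"]]]]),
    vm = parse_num("vm", TRUE),
    rm = parse_num("rm", TRUE),
    cm = parse_num("cm", TRUE),
    known_type = parse_chr("known_type"),
    series_resistance = parse_num("series_resistance", FALSE),
    holding_current = parse_num("holding_current", FALSE),
    reporter = parse_chr("reporter"),
    stringsAsFactors = FALSE
  )
  validate_cell_records(df)
}

#' Write a cell table to CSV
#'
#' Inverse of [read_cell_table()]: writes the canonical interface columns
#' with missing optional values as empty fields. Finite values round-trip
#' bit-compatibly (full precision via 17 significant digits).
#'
#' @param records a `cell_records` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(records, path) {
  records <- validate_cell_records(records)
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  out <- data.frame(
    cell_id = records$cell_id,
    genotype = records$genotype,
    vm_mV = fmt(records$vm),
    rm_MOhm = fmt(records$rm),
    cm_pF = fmt(records$cm),
    known_type = ifelse(is.na(records$known_type), "", records$known_type),
    series_resistance_MOhm = fmt(records$series_resistance),
    holding_current_pA = fmt(records$holding_current),
    reporter = ifelse(is.na(records$reporter), "", records$reporter),
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recording quality-control configuration
#'
#' Whole-cell recordings are excluded when the series resistance exceeds
#' `max_series_resistance` (default 20 MOhm) or the holding current at
#' -70 mV is more negative than `min_holding_current` (default -100 pA,
#' indicating a leaky seal). `combine_rule = "any_fails"` excludes a cell
#' when either criterion is violated; `"all_fail"` is the literal
#' conjunctive reading, excluding only when both are violated.
#'
#' @param max_series_resistance MOhm, must be positive.
#' @param min_holding_current pA; currents below (more negative than) this
#'   fail.
#' @param combine_rule `"any_fails"` (default) or `"all_fail"`.
#' @return a `qc_config` object.
#' @export
qc_config <- function(max_series_resistance = 20,
                      min_holding_current = -100,
                      combine_rule = c("any_fails", "all_fail")) {
  combine_rule <- match.arg(combine_rule)
  if (!is.numeric(max_series_resistance) || max_series_resistance <= 0) {
    stop("max_series_resistance must be positive", call. = FALSE)
  }
  structure(
    list(max_series_resistance = max_series_resistance,
         min_holding_current = min_holding_current,
         combine_rule = combine_rule),
    class = "qc_config"
  )
}

#' Quality-control filter for recorded cells
#'
#' Partitions records into kept and excluded sets. A cell with no QC fields
#' passes by default and is flagged `"unchecked"`. Filtering is total (no
#' errors) and idempotent: re-filtering the kept set changes nothing.
#'
#' @param records a `cell_records` table.
#' @param config a [qc_config()].
#' @return list with `kept` (a `cell_records` table with a `qc_status`
#'   column, `"passed"` or `"unchecked"`) and `excluded` (records plus a
#'   `qc_reason` column naming each violated criterion).
#' @export
qc_filter <- function(records, config = qc_config()) {
  records <- validate_cell_records(records)
  stopifnot(inherits(config, "qc_config"))
  sr_fail <- !is.na(records$series_resistance) &
    records$series_resistance > config$max_series_resistance
  hc_fail <- !is.na(records$holding_current) &
    records$holding_current < config$min_holding_current
  excluded <- switch(config$combine_rule,
    any_fails = sr_fail | hc_fail,
    all_fail = sr_fail & hc_fail
  )
  reason <- character(nrow(records))
  reason[sr_fail] <- "series_resistance"
  reason[hc_fail] <- paste0(ifelse(reason[hc_fail] == "", "",
                                   paste0(reason[hc_fail], ",")),
                            "holding_current")
  unchecked <- is.na(records$series_resistance) & is.na(records$holding_current)
  kept <- records[!excluded, , drop = FALSE]
  kept$qc_status <- ifelse(unchecked[!excluded], "unchecked", "passed")
  exc <- records[excluded, , drop = FALSE]
  exc$qc_reason <- reason[excluded]
  rownames(kept) <- NULL
  rownames(exc) <- NULL
  list(kept = kept, excluded = exc)
}
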