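#' Marker panel and phenotype groups of the reference MS study design
#'
#' The default immunophenotyping panel consists of 11 flow-cytometry
#' variables, each the percentage of gated cells positive for a cytokine or
#' transcription factor, measured on CD4+ T cells, CD14+ monocytes or CD19+
#' B cells.  Phenotype groups are the four multiple-sclerosis clinical
#' courses plus healthy controls.
#'
#' @return `ms_markers()` returns a character vector of 11 marker names;
#'   `ms_phenotypes()` the ordered five-group phenotype set
#'   (RR, BB, SP, PP, HC).
#' @export
ms_markers <- function() {
  c("CD4+RORC+", "CD4+IL17A+", "CD4+IL22+", "CD4+TBET+", "CD4+IL9+",
    "CD4+GATA+", "CD4+IL13+", "CD4+IL25+", "CD14+IL6+", "CD19+IL6+",
    "CD19+TGFb")
}

#' @rdname ms_markers
#' @export
ms_phenotypes <- function() c("RR", "BB", "SP", "PP", "HC")

#' Min-max scale a raw marker value onto [0, 1]
#'
#' Linear rescaling so that the observed minimum maps to 0 and the observed
#' maximum to 1.  Computation is kept at full floating-point precision;
#' two-decimal presentation is a separate concern handled by
#' [display_value()].
#'
#' @param x Raw value(s), must lie within `[lo, hi]`.
#' @param lo,hi Observed range bounds, `lo < hi`.
#' @param name Variable name used in error messages.
#' @return `(x - lo) / (hi - lo)`, in `[0, 1]`.
#' @examples
#' scale_minmax(25, 0.1, 60)   # 0.41569...
#' scale_minmax(60, 0.1, 60)   # 1
#' @export
scale_minmax <- function(x, lo, hi, name = "variable") {
  if (!is.numeric(x) || !is.numeric(lo) || !is.numeric(hi)) {
    stop("scale_minmax() expects numeric input for '", name, "'", call. = FALSE)
  }
  if (anyNA(x)) stop("missing value in '", name, "'; imputation is not supported",
                     call. = FALSE)
  if (hi <= lo) {
    stop("degenerate range for '", name, "': observed min ", lo,
         " is not below observed max ", hi, call. = FALSE)
  }
  if (any(x < lo) || any(x > hi)) {
    stop("value out of range for '", name, "': expected within [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  (x - lo) / (hi - lo)
}

#' Complement of a scaled value
#'
#' Maps a value scaled on `[0, 1]` to `1 - x`, the "low" coding of a
#' variable: where the scaled variable tracks high raw values, its
#' complement tracks low ones.  An involution: applying it twice returns
#' the input.
#'
#' @param x Scaled value(s) in `[0, 1]`.
#' @return `1 - x`, exactly.
#' @export
complement <- function(x) {
  if (!is.numeric(x)) stop("complement() expects numeric input", call. = FALSE)
  if (anyNA(x)) stop("missing value passed to complement()", call. = FALSE)
  if (any(x < 0) || any(x > 1)) {
    stop("complement() is defined on [0, 1]; got value outside that range",
         call. = FALSE)
  }
  1 - x
}

#' Two-decimal display form of a scaled value
#'
#' Formats a value in `[0, 1]` at two decimal places by truncation (floor),
#' not rounding: 0.41569 displays as "0.41".  A guard of 1e-9 absorbs
#' binary floating-point representation error (so 0.29 stored as
#' 28.999999...e-2 still displays as "0.29").
#'
#' @param x Numeric value(s) in `[0, 1]`.
#' @return Character vector, always with two decimals (e.g. `"1.00"`).
#' @examples
#' display_value(scale_minmax(25, 0.1, 60))  # "0.41"
#' @export
display_value <- function(x) {
  if (!is.numeric(x)) stop("display_value() expects numeric input", call. = FALSE)
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("display_value() is defined on [0, 1]", call. = FALSE)
  }
  sprintf("%.2f", floor(x * 100 + 1e-9) / 100)
}

#' One-hot phenotype indicator
#'
#' @param label Phenotype label, one of `groups`.
#' @param groups Ordered group set; defaults to [ms_phenotypes()].
#' @return Named binary vector with a single 1 at the label's position.
#' @export
encode_phenotype <- function(label, groups = ms_phenotypes()) {
  if (length(label) != 1L || !label %in% groups) {
    stop("unknown phenotype '", paste(label, collapse = ","),
         "'; accepted labels: ", paste(groups, collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(groups == label), groups)
}

#' Read a raw marker table from CSV
#'
#' Expected layout: header row with `subject_id`, `phenotype`, then one
#' column per marker.  With `require_panel = TRUE` the file must contain
#' exactly the 11-marker study panel ([ms_markers()]); a missing marker is
#' reported by name.
#'
#' @param path CSV file path (UTF-8, decimal point).
#' @param require_panel Enforce the full study panel.
#' @return A `data.frame` with columns `subject_id`, `phenotype` and the
#'   marker columns.
#' @export
read_marker_table <- function(path, require_panel = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (col in c("subject_id", "phenotype")) {
    if (!col %in% names(df)) {
      stop("marker table '", path, "' lacks required column '", col, "'",
           call. = FALSE)
    }
  }
  if (require_panel) {
    missing <- setdiff(ms_markers(), names(df))
    if (length(missing) > 0) {
      stop("marker table is missing marker column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    df <- df[, c("subject_id", "phenotype", ms_markers())]
  }
  validate_marker_table(df)
  df
}

validate_marker_table <- function(df) {
  markers <- setdiff(names(df), c("subject_id", "phenotype"))
  if (length(markers) == 0) stop("no marker columns found", call. = FALSE)
  bad <- setdiff(unique(df$phenotype), ms_phenotypes())
  if (length(bad) > 0) {
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(ms_phenotypes(), collapse = ", "), call. = FALSE)
  }
  for (m in markers) {
    v <- df[[m]]
    if (!is.numeric(v)) stop("marker column '", m, "' is not numeric", call. = FALSE)
    if (anyNA(v)) stop("missing value in marker column '", m,
                       "'; imputation is not supported", call. = FALSE)
    if (any(v < 0)) stop("negative value in marker column '", m, "'", call. = FALSE)
  }
  invisible(df)
}

#' Assemble the complement-coded scaled dataset
#'
#' Turns a raw marker table into the input matrix the Auto-Contractive Map
#' consumes.  Each marker column is min-max scaled over the cohort onto
#' `[0, 1]` and emitted twice: as `"high <marker>"` (the scaled value,
#' tracking high raw values) and `"low <marker>"` (its complement, tracking
#' low raw values), so both poles of every variable can occupy distinct
#' positions in the map.  Phenotype labels are appended as one binary
#' indicator variable per group.  An 11-marker panel thus becomes
#' 22 + 5 = 27 input variables.
#'
#' @param table Raw marker table (`data.frame` with `subject_id`,
#'   `phenotype` and marker columns), e.g. from [read_marker_table()].
#' @param groups Ordered phenotype group set.
#' @param bounds Optional scaling override: named list of `c(lo, hi)` per
#'   marker.  Defaults to the observed per-marker min/max of `table`, which
#'   is also what is recorded in the provenance.
#' @return A `scaled_dataset`: list with `records` (numeric matrix, rows =
#'   subjects, columns = variables, all entries in `[0, 1]`) and
#'   `variables` (data.frame of name, polarity `high`/`low`/`indicator`,
#'   source column and scaling bounds).
#' @export
assemble_dataset <- function(table, groups = ms_phenotypes(), bounds = NULL) {
  validate_marker_table(table)
  markers <- setdiff(names(table), c("subject_id", "phenotype"))
  if (nrow(table) < 2) stop("at least 2 subjects are required", call. = FALSE)

  n <- nrow(table)
  high <- matrix(NA_real_, n, length(markers))
  spec <- data.frame(name = character(0), polarity = character(0),
                     source = character(0), observed_min = numeric(0),
                     observed_max = numeric(0), stringsAsFactors = FALSE)
  for (j in seq_along(markers)) {
    m <- markers[j]
    v <- table[[m]]
    if (!is.null(bounds) && m %in% names(bounds)) {
      lo <- bounds[[m]][1]; hi <- bounds[[m]][2]
    } else {
      lo <- min(v); hi <- max(v)
    }
    if (hi <= lo) {
      stop("marker column '", m, "' is degenerate (constant); cannot scale",
           call. = FALSE)
    }
    high[, j] <- scale_minmax(v, lo, hi, name = m)
    spec <- rbind(spec,
                  data.frame(name = paste("high", m), polarity = "high",
                             source = m, observed_min = lo, observed_max = hi,
                             stringsAsFactors = FALSE),
                  data.frame(name = paste("low", m), polarity = "low",
                             source = m, observed_min = lo, observed_max = hi,
                             stringsAsFactors = FALSE))
  }
  low <- complement(high)

  ind <- t(vapply(table$phenotype, encode_phenotype, numeric(length(groups)),
                  groups = groups))
  spec <- rbind(spec, data.frame(name = groups, polarity = "indicator",
                                 source = "phenotype", observed_min = 0,
                                 observed_max = 1, stringsAsFactors = FALSE))

  # interleave high/low pairs to match the variable spec order
  records <- matrix(NA_real_, n, 2 * length(markers) + length(groups))
  records[, seq(1, by = 2, length.out = length(markers))] <- high
  records[, seq(2, by = 2, length.out = length(markers))] <- low
  records[, 2 * length(markers) + seq_along(groups)] <- ind
  colnames(records) <- spec$name
  rownames(records) <- as.character(table$subject_id)

  structure(list(records = records, variables = spec, groups = groups),
            class = "scaled_dataset")
}

#' @export
print.scaled_dataset <- function(x, ...) {
  cat("Scaled dataset:", nrow(x$records), "records x",
      ncol(x$records), "variables\n")
  cat("  ", sum(x$variables$polarity %in% c("high", "low")),
      "complement-coded marker variables,",
      sum(x$variables$polarity == "indicator"), "phenotype indicators\n")
  invisible(x)
}

#' Write / read a scaled dataset
#'
#' The records go to a full-precision CSV (one column per variable); the
#' variable specifications (polarity, source column, scaling bounds) go to
#' a JSON sidecar so that the exact transformation is recoverable.
#'
#' @param dataset A `scaled_dataset`.
#' @param csv_path Output CSV path.
#' @param provenance_path Output JSON path; defaults to `csv_path` with a
#'   `.provenance.json` suffix.
#' @return `write_scaled_dataset()` returns the paths invisibly;
#'   `read_scaled_dataset()` returns the `scaled_dataset`.
#' @export
write_scaled_dataset <- function(dataset, csv_path,
                                 provenance_path = paste0(csv_path, ".provenance.json")) {
  stopifnot(inherits(dataset, "scaled_dataset"))
  # 17 significant digits so the scaled values survive the text round trip
  # bit-for-bit and retraining from the CSV reproduces the model
  rec_chr <- apply(dataset$records, 2, function(x) sprintf("%.17g", x))
  df <- data.frame(subject_id = rownames(dataset$records),
                   rec_chr, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(variables = dataset$variables, groups = dataset$groups),
    provenance_path, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv_path, provenance = provenance_path))
}

#' @rdname write_scaled_dataset
#' @export
read_scaled_dataset <- function(csv_path,
                                provenance_path = paste0(csv_path, ".provenance.json")) {
  df <- utils::read.csv(csv_path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  prov <- jsonlite::read_json(provenance_path, simplifyVector = TRUE)
  records <- as.matrix(df[, prov$variables$name, drop = FALSE])
  rownames(records) <- as.character(df$subject_id)
  structure(list(records = records, variables = prov$variables,
                 groups = prov$groups),
            class = "scaled_dataset")
}

#' Recover raw marker values from a scaled dataset
#'
#' Inverts the min-max scaling of the `high` variables using the stored
#' bounds; used for provenance checks.
#'
#' @param dataset A `scaled_dataset`.
#' @return Matrix of raw marker values (subjects x markers).
#' @export
unscale_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "scaled_dataset"))
  hi_vars <- dataset$variables[dataset$variables$polarity == "high", ]
  out <- sapply(seq_len(nrow(hi_vars)), function(i) {
    v <- dataset$records[, hi_vars$name[i]]
    v * (hi_vars$observed_max[i] - hi_vars$observed_min[i]) + hi_vars$observed_min[i]
  })
  out <- matrix(out, nrow = nrow(dataset$records))
  colnames(out) <- hi_vars$source
  rownames(out) <- rownames(dataset$records)
  out
}
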