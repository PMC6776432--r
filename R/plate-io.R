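# Plate-level data model: one row per qPCR well, canonical columns
#   target, standard, plate, instrument, operator, replicate,
#   ct, tm, wt_copies, truth_copies, seq_confirmed
# An absent Ct (NA) means "no amplification signal"; Ct = 0 is a parse error
# because the dropout statistic needs an unambiguous empty state.

PLATE_COLUMNS <- c("target", "standard", "plate", "instrument", "operator",
                   "replicate", "ct", "tm", "wt_copies", "truth_copies",
                   "seq_confirmed")

#' Construct a well-level plate table
#'
#' Builds (and validates) the canonical tibble of qPCR well records used by
#' every downstream statistic. Each row is one well. `ct = NA` encodes an
#' empty (non-amplifying) well; such wells must also have `tm = NA`.
#'
#' @param target Assay target label, one of [ASSAY_TARGETS].
#' @param standard Standard level label (`"A"`–`"G"`, `"WT_ONLY"`, `"NTC"`).
#' @param plate,instrument,operator Run identifiers (coerced to character).
#' @param replicate Positive integer replicate index within the cell.
#' @param ct Threshold cycle, `NA` for no amplification; must lie in
#'   `(0, max_cycles)` when present.
#' @param tm Melt-peak temperature in degrees Celsius, `NA` when absent;
#'   must lie in 50–100 when present.
#' @param wt_copies Non-negative wild-type background copies in the well.
#' @param truth_copies Nominal mean mutant copies for simulated/control
#'   wells (`NA` for unknowns).
#' @param seq_confirmed Logical sequencing-confirmation flag (`NA` when the
#'   well was not sequenced).
#' @param max_cycles Upper Ct bound used for validation (default 45 cycles).
#'
#' @return A tibble with the canonical plate columns.
#' @export
well_table <- function(target, standard, plate = "P1", instrument = "I1",
                       operator = "O1", replicate = 1L, ct = NA_real_,
                       tm = NA_real_, wt_copies = 0L, truth_copies = NA_real_,
                       seq_confirmed = NA, max_cycles = 45) {
  tbl <- tibble::tibble(
    target = as.character(target),
    standard = as.character(standard),
    plate = as.character(plate),
    instrument = as.character(instrument),
    operator = as.character(operator),
    replicate = as.integer(replicate),
    ct = as.numeric(ct),
    tm = as.numeric(tm),
    wt_copies = as.numeric(wt_copies),
    truth_copies = as.numeric(truth_copies),
    seq_confirmed = as.logical(seq_confirmed)
  )
  validate_wells(tbl, max_cycles = max_cycles)
}

#' Validate a plate table against the well-record invariants
#'
#' @param wells A data frame with the canonical plate columns.
#' @param max_cycles Upper Ct bound (exclusive).
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_wells <- function(wells, max_cycles = 45) {
  missing <- setdiff(PLATE_COLUMNS, names(wells))
  if (length(missing) > 0) {
    abort(paste0("plate table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "poisqpcr_schema_error")
  }
  wells <- tibble::as_tibble(wells)
  bad_target <- setdiff(unique(wells$target), ASSAY_TARGETS)
  if (length(bad_target) > 0) {
    abort(paste0("unknown assay target(s): ", paste(bad_target, collapse = ", ")),
          class = "poisqpcr_schema_error")
  }
  ct <- wells$ct
  if (any(!is.na(ct) & (ct <= 0 | ct >= max_cycles))) {
    abort(sprintf("ct values must lie in (0, %g) when present", max_cycles),
          class = "poisqpcr_domain_error")
  }
  tm <- wells$tm
  if (any(!is.na(tm) & (tm < 50 | tm > 100))) {
    abort("tm values must lie in [50, 100] degrees C when present",
          class = "poisqpcr_domain_error")
  }
  if (any(is.na(ct) & !is.na(tm))) {
    abort("a well with absent ct cannot carry a melt temperature",
          class = "poisqpcr_domain_error")
  }
  if (any(is.na(wells$replicate) | wells$replicate < 1)) {
    abort("replicate index must be >= 1", class = "poisqpcr_domain_error")
  }
  if (any(!is.na(wells$wt_copies) & wells$wt_copies < 0)) {
    abort("wt_copies must be non-negative", class = "poisqpcr_domain_error")
  }
  wells
}

#' Read a plate-level CSV of qPCR well results
#'
#' Parses a UTF-8, comma-separated table with a header row into the
#' canonical well tibble. Blank `ct` cells map to `NA` (an informative
#' empty well). A literal `ct` of 0 is rejected: the occupancy statistics
#' require "no signal" to be encoded by absence, never by zero.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), for files whose
#'   headers differ from the canonical ones.
#' @param max_cycles Upper Ct bound used for validation.
#'
#' @return A tibble of well records, one per data row, row order preserved.
#' @export
read_plate_table <- function(path, schema = NULL, max_cycles = 45) {
  if (!file.exists(path)) {
    abort(paste0("plate table not found: ", path), class = "poisqpcr_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    have <- intersect(unname(schema), names(raw))
    raw <- dplyr::rename(raw, !!!schema[schema %in% have])
  }
  missing <- setdiff(PLATE_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("plate table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "poisqpcr_schema_error")
  }
  parse_num <- function(x, col) {
    x <- trimws(x)
    x[!is.na(x) & x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric %s value '%s' at data row %d", col, x[bad[1]], bad[1]),
            class = "poisqpcr_parse_error")
    }
    out
  }
  ct <- parse_num(raw$ct, "ct")
  if (any(!is.na(ct) & ct == 0)) {
    row <- which(!is.na(ct) & ct == 0)[1]
    abort(sprintf("ct = 0 at data row %d: empty wells must have a blank ct cell", row),
          class = "poisqpcr_parse_error")
  }
  seq_chr <- trimws(raw$seq_confirmed)
  seq_chr[!is.na(seq_chr) & seq_chr == ""] <- NA_character_
  out <- tibble::tibble(
    target = raw$target,
    standard = raw$standard,
    plate = raw$plate,
    instrument = raw$instrument,
    operator = raw$operator,
    replicate = as.integer(parse_num(raw$replicate, "replicate")),
    ct = ct,
    tm = parse_num(raw$tm, "tm"),
    wt_copies = parse_num(raw$wt_copies, "wt_copies"),
    truth_copies = parse_num(raw$truth_copies, "truth_copies"),
    seq_confirmed = as.logical(seq_chr)
  )
  validate_wells(out, max_cycles = max_cycles)
}

#' Write a plate table as CSV
#'
#' Inverse of [read_plate_table()]: empty wells are written with blank `ct`
#' and `tm` cells so a round trip reproduces every field.
#'
#' @param wells Canonical well tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(wells, path) {
  readr::write_csv(wells[PLATE_COLUMNS], path, na = "")
  invisible(path)
}

#' QC configuration for plate data
#'
#' Bundles the Ct and melt-temperature acceptance windows applied before
#' any statistic. A minimum Ct guards against spurious early signals
#' (primer dimers, threshold artifacts); the melt window distinguishes the
#' specific amplicon from non-specific products. Melt windows are
#' per-assay configuration values: they depend on amplicon composition and
#' ship here as example defaults, not measured values.
#'
#' @param min_ct Wells with `ct <= min_ct` are flagged (default 10).
#' @param max_ct Wells with `ct >= max_ct` are flagged (default 45).
#' @param tm_window Named list mapping assay target to `c(low, high)` melt
#'   window in degrees C. The default gives every target 78–82.
#'
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(min_ct = 10, max_ct = 45,
                      tm_window = NULL) {
  if (!(min_ct > 0 && max_ct > min_ct)) {
    abort("need 0 < min_ct < max_ct", class = "poisqpcr_config_error")
  }
  if (is.null(tm_window)) {
    tm_window <- stats::setNames(rep(list(c(78, 82)), length(ASSAY_TARGETS)),
                                 ASSAY_TARGETS)
  }
  for (w in tm_window) {
    if (length(w) != 2 || !(w[1] < w[2])) {
      abort("each tm_window must be c(low, high) with low < high",
            class = "poisqpcr_config_error")
    }
  }
  structure(list(min_ct = min_ct, max_ct = max_ct, tm_window = tm_window),
            class = "qc_config")
}

#' Apply QC filters to a plate table
#'
#' Splits wells into QC-passing and flagged sets. Wells with an absent Ct
#' pass: they are informative empty wells for the occupancy model, not QC
#' failures. Flag precedence is fixed (`min_ct`, then `max_ct`, then
#' `tm_out_of_window`) so each flagged well carries exactly one primary
#' reason and the split is deterministic.
#'
#' @param wells Canonical well tibble.
#' @param qc A [qc_config()] object.
#'
#' @return A list with elements `passing` (tibble) and `flagged` (tibble
#'   with an added `reason` column).
#' @export
apply_qc <- function(wells, qc = qc_config()) {
  stopifnot(inherits(qc, "qc_config"))
  wells <- validate_wells(wells, max_cycles = Inf)
  unknown <- setdiff(unique(wells$target[!is.na(wells$tm)]), names(qc$tm_window))
  if (length(unknown) > 0) {
    abort(paste0("no tm_window configured for target(s): ",
                 paste(unknown, collapse = ", ")),
          class = "poisqpcr_config_error")
  }
  lo <- vapply(wells$target, function(t) {
    w <- qc$tm_window[[t]]
    if (is.null(w)) NA_real_ else w[1]
  }, numeric(1))
  hi <- vapply(wells$target, function(t) {
    w <- qc$tm_window[[t]]
    if (is.null(w)) NA_real_ else w[2]
  }, numeric(1))
  has_ct <- !is.na(wells$ct)
  reason <- rep(NA_character_, nrow(wells))
  reason[has_ct & wells$ct <= qc$min_ct] <- "min_ct"
  flag <- has_ct & wells$ct >= qc$max_ct & is.na(reason)
  reason[flag] <- "max_ct"
  tm_bad <- has_ct & !is.na(wells$tm) & (wells$tm < lo | wells$tm > hi) &
    is.na(reason)
  reason[tm_bad] <- "tm_out_of_window"
  flagged <- wells[!is.na(reason), , drop = FALSE]
  flagged$reason <- reason[!is.na(reason)]
  list(passing = wells[is.na(reason), , drop = FALSE], flagged = flagged)
}

# Rendering helpers shared by the report writers ------------------------------

#' Render an occupancy lambda for reports
#'
#' A plate with zero empty wells gives an unbounded dropout estimate
#' (-log of zero); reports render the conventional ">10" sentinel rather
#' than a number.
#'
#' @param lambda Numeric vector; `Inf` encodes the zero-empty sentinel.
#' @param digits Decimal places for finite values.
#' @return Character vector.
#' @export
format_lambda <- function(lambda, digits = 2) {
  out <- ifelse(is.infinite(lambda), ">10",
                formatC(round(lambda, digits), format = "fg"))
  as.character(out)
}

#' Write named result tables to TSV or JSON
#'
#' Emits each table deterministically: rows are sorted by assay target and
#' standard level when those columns exist, and numeric columns are
#' rendered at fixed precision so identical inputs yield byte-identical
#' files. Columns named `lambda_dropout` are rendered through
#' [format_lambda()] (zero-empty cells become `">10"`).
#'
#' @param tables Named list of data frames (must be non-empty).
#' @param path Output file path. With `format = "tsv"` and several tables,
#'   the tables are written as named blocks separated by `## <name>` header
#'   lines; with one table a plain TSV is written.
#' @param format `"tsv"` or `"json"`.
#' @param digits Decimal places used for numeric rendering (default 4).
#' @return `path`, invisibly.
#' @export
write_report <- function(tables, path, format = c("tsv", "json"), digits = 4) {
  format <- match.arg(format)
  if (!is.list(tables) || length(tables) == 0 || is.null(names(tables)) ||
      any(names(tables) == "")) {
    abort("tables must be a non-empty named list of data frames",
          class = "poisqpcr_domain_error")
  }
  prep <- lapply(tables, function(tbl) {
    tbl <- tibble::as_tibble(tbl)
    ord <- intersect(c("target", "standard"), names(tbl))
    if (length(ord) > 0) {
      tbl <- dplyr::arrange(tbl, dplyr::across(dplyr::all_of(ord)))
    }
    if ("lambda_dropout" %in% names(tbl) && is.numeric(tbl$lambda_dropout)) {
      tbl$lambda_dropout <- format_lambda(tbl$lambda_dropout)
    }
    num <- vapply(tbl, is.numeric, logical(1))
    tbl[num] <- lapply(tbl[num], function(x) round(x, digits))
    tbl
  })
  if (format == "json") {
    jsonlite::write_json(prep, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    single <- length(prep) == 1
    for (nm in names(prep)) {
      if (!single) writeLines(paste0("## ", nm), con)
      tbl <- prep[[nm]]
      chr <- lapply(tbl, function(x) {
        out <- as.character(x)
        out[is.na(out)] <- ""
        out
      })
      writeLines(paste(names(tbl), collapse = "\t"), con)
      if (nrow(tbl) > 0) {
        writeLines(do.call(paste, c(chr, sep = "\t")), con)
      }
      if (!single) writeLines("", con)
    }
  }
  invisible(path)
}
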