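#' @keywords internal
RESPONSE_NAMES <- c("log_Kp", "log_KaHSA", "log_BB", "caco2_e06", "fu_brain")

#' @keywords internal
DESCRIPTOR_NAMES <- c("log_km", "log_k01", "log_kw_iam", "log_kw_ods",
                      "tpsa", "alpha", "mw")

RETENTION_SYSTEMS <- c("MLC", "IAM", "ODS")
X_KINDS <- c("surfactant_molarity", "modifier_volume_fraction")

#' Assemble a compound table
#'
#' A `compound_table` bundles three aligned pieces: one row per compound of
#' identity, structural/electronic descriptors and pharmacokinetic
#' responses; a long-format table of chromatographic retention series; and a
#' per-compound table of derived chromatographic descriptors (`log_km`,
#' `log_k01`, `log_kw_iam`, `log_kw_ods`). All pieces are keyed by
#' `compound_id`.
#'
#' @param compounds Data frame with columns `compound_id`, `mw`, `tpsa`,
#'   `alpha` and optionally `series`, `substituent`, `log_p` and any of the
#'   responses `log_Kp`, `log_KaHSA`, `log_BB`, `caco2_e06`, `fu_brain`.
#'   Missing response values (`NA`) are allowed and excluded pairwise when a
#'   model is fitted.
#' @param retention Optional long-format data frame with columns
#'   `compound_id`, `system` (one of `"MLC"`, `"IAM"`, `"ODS"`), `x_kind`
#'   (`"surfactant_molarity"` in mol/L or `"modifier_volume_fraction"`), `x`
#'   and `k` (retention factor, dimensionless, > 0).
#' @param descriptors Optional data frame with `compound_id` plus derived
#'   descriptor columns.
#'
#' @return An object of class `compound_table`.
#' @export
compound_table <- function(compounds, retention = NULL, descriptors = NULL) {
  compounds <- as_tibble(compounds)
  retention <- if (is.null(retention)) {
    tibble(compound_id = character(), system = character(),
           x_kind = character(), x = double(), k = double())
  } else {
    as_tibble(retention)
  }
  descriptors <- if (is.null(descriptors)) {
    tibble(compound_id = compounds$compound_id)
  } else {
    as_tibble(descriptors)
  }
  x <- structure(
    list(compounds = compounds, retention = retention,
         descriptors = descriptors),
    class = "compound_table"
  )
  validate_compound_table(x)
  x
}

#' Validate a compound table
#'
#' Checks the structural invariants: required columns present, positive
#' molecular weight and polarizability, non-negative TPSA, `fu_brain` within
#' `[0, 1]`, unique compound ids, positive retention factors, non-negative
#' concentrations, and that every retention series and descriptor row
#' references a known compound.
#'
#' @param x A [compound_table()].
#' @return `x`, invisibly, if valid; otherwise an error of class
#'   `mlcqsar_validation_error` (or `mlcqsar_schema_error` for missing
#'   columns).
#' @export
validate_compound_table <- function(x) {
  cmp <- x$compounds
  for (col in c("compound_id", "mw", "tpsa", "alpha")) {
    if (!col %in% names(cmp)) {
      abort(sprintf("compound table is missing required column '%s'", col),
            class = "mlcqsar_schema_error")
    }
  }
  for (col in intersect(c("mw", "tpsa", "alpha", "log_p", RESPONSE_NAMES),
                        names(cmp))) {
    if (nrow(cmp) && !is.numeric(cmp[[col]])) {
      abort(sprintf("column '%s' must be numeric", col),
            class = "mlcqsar_parse_error")
    }
  }
  if (anyDuplicated(cmp$compound_id)) {
    dup <- unique(cmp$compound_id[duplicated(cmp$compound_id)])
    abort(sprintf("duplicated compound_id: %s", paste(dup, collapse = ", ")),
          class = "mlcqsar_validation_error")
  }
  if (any(!is.na(cmp$mw) & cmp$mw <= 0)) {
    abort("mw must be > 0", class = "mlcqsar_validation_error")
  }
  if (any(!is.na(cmp$tpsa) & cmp$tpsa < 0)) {
    abort("tpsa must be >= 0", class = "mlcqsar_validation_error")
  }
  if (any(!is.na(cmp$alpha) & cmp$alpha <= 0)) {
    abort("alpha must be > 0", class = "mlcqsar_validation_error")
  }
  if ("fu_brain" %in% names(cmp)) {
    bad <- !is.na(cmp$fu_brain) & (cmp$fu_brain < 0 | cmp$fu_brain > 1)
    if (any(bad)) {
      abort(sprintf("fu_brain must lie in [0, 1]; offending compound(s): %s",
                    paste(cmp$compound_id[bad], collapse = ", ")),
            class = "mlcqsar_validation_error")
    }
  }

  ret <- x$retention
  if (nrow(ret)) {
    for (col in c("compound_id", "system", "x_kind", "x", "k")) {
      if (!col %in% names(ret)) {
        abort(sprintf("retention table is missing required column '%s'", col),
              class = "mlcqsar_schema_error")
      }
    }
    if (nrow(ret) && (!is.numeric(ret$x) || !is.numeric(ret$k))) {
      abort("retention columns x and k must be numeric",
            class = "mlcqsar_parse_error")
    }
    if (any(!ret$system %in% RETENTION_SYSTEMS)) {
      abort(sprintf("retention system must be one of %s",
                    paste(RETENTION_SYSTEMS, collapse = ", ")),
            class = "mlcqsar_validation_error")
    }
    if (any(!ret$x_kind %in% X_KINDS)) {
      abort(sprintf("x_kind must be one of %s", paste(X_KINDS, collapse = ", ")),
            class = "mlcqsar_validation_error")
    }
    bad_k <- which(is.na(ret$k) | ret$k <= 0)
    if (length(bad_k)) {
      i <- bad_k[1]
      abort(sprintf(
        "retention factor must be > 0; compound '%s' at x = %g has k = %s",
        ret$compound_id[i], ret$x[i], format(ret$k[i])),
        class = "mlcqsar_validation_error")
    }
    if (any(is.na(ret$x) | ret$x < 0)) {
      abort("concentrations x must be >= 0", class = "mlcqsar_validation_error")
    }
    orphan <- setdiff(unique(ret$compound_id), cmp$compound_id)
    if (length(orphan)) {
      abort(sprintf("retention series reference unknown compound_id: %s",
                    paste(orphan, collapse = ", ")),
            class = "mlcqsar_validation_error")
    }
  }

  des <- x$descriptors
  if (!"compound_id" %in% names(des)) {
    abort("descriptor table is missing required column 'compound_id'",
          class = "mlcqsar_schema_error")
  }
  orphan <- setdiff(des$compound_id, cmp$compound_id)
  if (length(orphan)) {
    abort(sprintf("descriptor rows reference unknown compound_id: %s",
                  paste(orphan, collapse = ", ")),
          class = "mlcqsar_validation_error")
  }
  invisible(x)
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("<compound_table: %d compounds, %d retention measurements>\n",
              nrow(x$compounds), nrow(x$retention)))
  resp <- intersect(RESPONSE_NAMES, names(x$compounds))
  if (length(resp)) cat("  responses:  ", paste(resp, collapse = ", "), "\n")
  des <- setdiff(names(x$descriptors), "compound_id")
  if (length(des)) cat("  descriptors:", paste(des, collapse = ", "), "\n")
  invisible(x)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

read_table_strict <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "mlcqsar_io_error")
  }
  delim <- delim %||% detect_delim(path)
  out <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_guess()),
    locale = readr::locale(decimal_mark = ".", grouping_mark = ""),
    show_col_types = FALSE, progress = FALSE
  )
  probs <- readr::problems(out)
  if (nrow(probs)) {
    abort(sprintf("failed to parse %s: %s (row %d, col %d)",
                  path, probs$expected[1], probs$row[1], probs$col[1]),
          class = "mlcqsar_parse_error")
  }
  out
}

#' Read a compound table from delimiter-separated text
#'
#' Reads the wide compound file (and, optionally, the long retention file
#' and the derived-descriptor file) written by [write_compound_table()].
#' The delimiter is auto-detected between comma and tab unless given.
#' Numeric parsing uses `.` as the decimal mark; cells with thousands
#' separators or other malformed numbers raise a parse error.
#'
#' @param path Path to the compound CSV/TSV (one row per compound).
#' @param retention Optional path to the long-format retention table
#'   (`compound_id`, `system`, `x_kind`, `x`, `k`).
#' @param descriptors Optional path to the derived-descriptor table.
#' @param delim Field delimiter; `NULL` (default) auto-detects.
#' @return A validated [compound_table()].
#' @export
read_compound_table <- function(path, retention = NULL, descriptors = NULL,
                                delim = NULL) {
  cmp <- read_table_strict(path, delim)
  if ("compound_id" %in% names(cmp)) {
    cmp$compound_id <- as.character(cmp$compound_id)
  }
  ret <- des <- NULL
  if (!is.null(retention)) {
    ret <- read_table_strict(retention, delim)
    ret$compound_id <- as.character(ret$compound_id)
  }
  if (!is.null(descriptors)) {
    des <- read_table_strict(descriptors, delim)
    des$compound_id <- as.character(des$compound_id)
  }
  compound_table(cmp, ret, des)
}

#' Write a compound table to delimiter-separated text
#'
#' The inverse of [read_compound_table()]: values round-trip at full
#' numeric precision (`read(write(x))` reproduces `x` exactly).
#'
#' @param table A [compound_table()].
#' @param path Output path for the compound file.
#' @param retention,descriptors Optional output paths for the retention and
#'   derived-descriptor tables.
#' @param delim Field delimiter (default comma).
#' @return `table`, invisibly.
#' @export
write_compound_table <- function(table, path, retention = NULL,
                                 descriptors = NULL, delim = ",") {
  validate_compound_table(table)
  readr::write_delim(table$compounds, path, delim = delim)
  if (!is.null(retention)) {
    readr::write_delim(table$retention, retention, delim = delim)
  }
  if (!is.null(descriptors)) {
    readr::write_delim(table$descriptors, descriptors, delim = delim)
  }
  invisible(table)
}

#' The bundled 19-compound chromatography/pharmacokinetics dataset
#'
#' Loads the packaged dataset of 19 fused azaisocytosine-containing
#' congeners (three structural series A, B, C): molecular weight, TPSA,
#' polarizability, in-silico log P and five pharmacokinetic responses per
#' compound; micellar (Brij 35) retention factors at 0.075, 0.100, 0.125 and
#' 0.150 mol/L; and the chromatographic descriptors `log_km` (zero-micelle
#' retention from the Foley model), `log_kw_iam` and `log_kw_ods`
#' (aqueous-eluent extrapolations on IAM and end-capped ODS phases). The
#' descriptor `log_k01` -- log10 of the retention factor in the 0.1 mol/L
#' micellar eluent -- is computed from the retention table on load. The
#' descriptor table also carries `foley_r_squared`, the source study's
#' coefficient of determination for each compound's Foley fit, for
#' comparison with [fit_foley_batch()].
#'
#' TPSA values for compounds 16, 17 and 19 are normalized from the source's
#' typographic decimal commas ("74,57") to 74.57, consistent with the rest
#' of the column.
#'
#' @return A validated [compound_table()] with 19 records.
#' @export
bundled_paper_dataset <- function() {
  ext <- function(f) system.file("extdata", f, package = "mlcqsar",
                                 mustWork = TRUE)
  tab <- read_compound_table(
    ext("compounds.csv"),
    retention = ext("retention_mlc.csv"),
    descriptors = ext("chromatographic_descriptors.csv")
  )
  k01 <- tab$retention[tab$retention$system == "MLC" &
                         abs(tab$retention$x - 0.1) < 1e-9, ]
  tab$descriptors$log_k01 <-
    log10(k01$k[match(tab$descriptors$compound_id, k01$compound_id)])
  validate_compound_table(tab)
  tab
}

#' Extract one retention series
#'
#' @param table A [compound_table()].
#' @param compound_id Compound label.
#' @param system Chromatographic system (`"MLC"`, `"IAM"` or `"ODS"`).
#' @return A tibble of the series rows sorted by `x`.
#' @export
retention_series <- function(table, compound_id, system = "MLC") {
  ret <- table$retention
  out <- ret[ret$compound_id == compound_id & ret$system == system, ]
  out[order(out$x), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
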