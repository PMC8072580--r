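reference_path <- function(f) {
  system.file("extdata", f, package = "mlcqsar", mustWork = TRUE)
}

#' Published reference statistics bundled with the package
#'
#' `reference_fit_stats()` returns the per-equation global statistics of
#' the source study (label, response, predictor set, n, R2, sd, integer F,
#' p, VIF bound, adjusted R2, PRESS, MSE); `reference_coefficients()` the
#' per-term coefficient and standard-error values. Numeric columns are kept
#' as printed strings so that comparisons can honor the published decimal
#' precision; convert with `as.numeric()` where needed.
#'
#' @return A tibble.
#' @export
reference_fit_stats <- function() {
  readr::read_csv(reference_path("reference_fit_stats.csv"),
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' @rdname reference_fit_stats
#' @export
reference_coefficients <- function() {
  readr::read_csv(reference_path("reference_coefficients.csv"),
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Tolerance implied by a printed value
#'
#' The package's policy for matching published numbers: a computed value
#' matches a printed one when it differs by at most `units` units in the
#' last printed decimal place (default 1.5, covering round-off in the
#' published table).
#'
#' @param printed The printed value, as the string carrying its decimals
#'   (e.g. `"0.108"` allows +-0.0015).
#' @param units Half-width in last-decimal units.
#' @return `printed_tolerance()`: the numeric half-width.
#' @export
printed_tolerance <- function(printed, units = 1.5) {
  decimals <- vapply(as.character(printed), function(s) {
    s <- sub("^[^.]*", "", s)
    if (nchar(s)) nchar(s) - 1L else 0L
  }, integer(1))
  units * 10^(-decimals)
}

#' @rdname printed_tolerance
#' @param computed Computed numeric value(s).
#' @return `matches_printed()`: logical, `TRUE` where `computed` is within
#'   tolerance of the printed value.
#' @export
matches_printed <- function(computed, printed, units = 1.5) {
  abs(computed - as.numeric(printed)) <= printed_tolerance(printed, units)
}

#' Pipeline run configuration
#'
#' Collects everything [run_pipeline()] needs: the input tables (or
#' `"bundled"` for the packaged dataset), the CMC used when refitting the
#' micellar model, the list of model specifications, the output directory,
#' and whether figures are rendered.
#'
#' `load_run_config()` reads the same fields from a YAML or JSON file;
#' `model_specs` entries there are maps with `response`, `predictors` and
#' optional `label`.
#'
#' @param input `"bundled"` or a named list with `compounds` and optionally
#'   `retention`, `descriptors` file paths.
#' @param model_specs List of [model_spec()] objects; defaults to the
#'   twenty study specifications.
#' @param cmc Critical micelle concentration (mol/L) for Foley refits.
#' @param output_dir Directory for reports and figures (created if absent).
#' @param figures Render figure files? (default `TRUE`).
#' @param tolerance_units Last-decimal units for reproduce-paper
#'   comparisons.
#' @param seed Seed applied before any synthetic stage.
#' @return A `run_config` object.
#' @export
run_config <- function(input = "bundled", model_specs = paper_model_specs(),
                       cmc = 0, output_dir = tempfile("mlcqsar_run_"),
                       figures = TRUE, tolerance_units = 1.5, seed = 1L) {
  if (!length(model_specs)) {
    abort("model_specs must be non-empty", class = "mlcqsar_spec_error")
  }
  structure(list(input = input, model_specs = model_specs, cmc = cmc,
                 output_dir = output_dir, figures = figures,
                 tolerance_units = tolerance_units, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a `.yml`/`.yaml` or `.json` configuration file.
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be a .yaml or .json file", class = "mlcqsar_io_error")
  }
  raw_specs <- raw$model_specs
  if (is.data.frame(raw_specs)) {
    # JSON arrays of objects simplify to a data frame; re-split by row
    raw_specs <- lapply(seq_len(nrow(raw_specs)), function(i) {
      list(response = raw_specs$response[i],
           predictors = unlist(raw_specs$predictors[i]),
           label = raw_specs$label[i])
    })
  }
  specs <- if (is.null(raw_specs)) {
    paper_model_specs()
  } else {
    lapply(raw_specs, function(s) {
      model_spec(s$response, unlist(s$predictors), label = s$label)
    })
  }
  run_config(
    input = raw$input %||% "bundled",
    model_specs = specs,
    cmc = raw$cmc %||% 0,
    output_dir = raw$output_dir %||% tempfile("mlcqsar_run_"),
    figures = raw$figures %||% TRUE,
    tolerance_units = raw$tolerance_units %||% 1.5,
    seed = raw$seed %||% 1L
  )
}

resolve_input_table <- function(input) {
  if (identical(input, "bundled")) return(bundled_paper_dataset())
  if (inherits(input, "compound_table")) return(input)
  read_compound_table(input$compounds, retention = input$retention,
                      descriptors = input$descriptors)
}

ensure_log_k01 <- function(table) {
  if ("log_k01" %in% names(table$descriptors)) return(table)
  mlc <- table$retention[table$retention$system == "MLC" &
                           abs(table$retention$x - 0.1) < 1e-9, ]
  if (nrow(mlc)) {
    table$descriptors$log_k01 <-
      log10(mlc$k[match(table$descriptors$compound_id, mlc$compound_id)])
  }
  table
}

#' Run the full chromatography-to-QSAR pipeline
#'
#' End to end: load the input tables, refit the micellar binding model per
#' compound (reported alongside any descriptor values carried by the data),
#' derive `log_k01` from the 0.1 mol/L micellar column when absent, fit
#' every model specification, validate each by leave-one-out
#' cross-validation and VIF, compute the applicability-domain table, render
#' figures, and write machine-readable reports (`models.csv`,
#' `validation.csv`, `applicability.csv`, `summary.json`) into the output
#' directory. A failure in one specification is recorded in the summary and
#' does not abort the others. Two runs on identical inputs produce
#' byte-identical `summary.json` files.
#'
#' @param config A [run_config()], or a path accepted by
#'   [load_run_config()].
#' @return Invisibly, a list with `models`, `validation`, `ad` (per-spec
#'   lists), `foley` (batch fit result or `NULL`), `summary` (tibble) and
#'   `output_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  table <- resolve_input_table(config$input)
  table <- ensure_log_k01(table)
  foley <- NULL
  if (any(table$retention$system == "MLC")) {
    foley <- fit_foley_batch(table, cmc = config$cmc)
    table <- foley$table
    readr::write_csv(foley$summary,
                     file.path(config$output_dir, "foley_fits.csv"))
  }

  models <- list(); validations <- list(); ads <- list()
  rows <- list()
  for (spec in config$model_specs) {
    lbl <- spec$label
    res <- tryCatch({
      m <- fit_mlr(table, spec)
      v <- loo_validate(m)
      a <- williams_data(m)
      list(model = m, validation = v, ad = a)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[lbl]] <- tibble(
        label = lbl, status = "failed", equation = NA_character_,
        n = NA_integer_, r_squared = NA_real_, adj_r_squared = NA_real_,
        sd = NA_real_, f = NA_real_, p = NA_real_, max_vif = NA_real_,
        press = NA_real_, q_squared = NA_real_, mse_resid = NA_real_,
        mse_cv = NA_real_, h_star = NA_real_, n_outliers = NA_integer_,
        message = conditionMessage(res))
      next
    }
    models[[lbl]] <- res$model
    validations[[lbl]] <- res$validation
    ads[[lbl]] <- res$ad
    rows[[lbl]] <- tibble(
      label = lbl, status = "ok", equation = equation_string(res$model),
      n = res$model$n, r_squared = res$model$r_squared,
      adj_r_squared = res$model$adj_r_squared, sd = res$model$sd_resid,
      f = res$model$f_stat, p = res$model$p_value,
      max_vif = if (is.null(res$validation$vif)) NA_real_
                else max(res$validation$vif),
      press = res$validation$press, q_squared = res$validation$q_squared,
      mse_resid = res$validation$mse_resid, mse_cv = res$validation$mse_cv,
      h_star = attr(res$ad, "h_star"),
      n_outliers = sum(res$ad$leverage_outlier | res$ad$residual_outlier),
      message = NA_character_)
    if (config$figures) {
      for (f in c("predicted_vs_actual", "standardized_coefficients",
                  "williams")) {
        plot_fun <- switch(f,
          predicted_vs_actual = plot_predicted_vs_actual(res$model),
          standardized_coefficients =
            plot_standardized_coefficients(res$model),
          williams = plot_williams(res$ad))
        ggplot2::ggsave(
          file.path(config$output_dir, sprintf("%s_%s.png", lbl, f)),
          plot_fun, width = 5, height = 4, dpi = 150)
      }
    }
  }
  summary <- dplyr::bind_rows(rows)

  model_report <- summary[, c("label", "status", "equation", "n",
                              "r_squared", "sd", "f", "p", "max_vif")]
  validation_report <- summary[, c("label", "status", "adj_r_squared",
                                   "press", "mse_resid", "q_squared",
                                   "mse_cv")]
  ad_report <- dplyr::bind_rows(lapply(names(ads), function(lbl) {
    out <- as_tibble(ads[[lbl]])
    out$label <- lbl
    out$h_star <- attr(ads[[lbl]], "h_star")
    out
  }))
  readr::write_csv(model_report, file.path(config$output_dir, "models.csv"))
  readr::write_csv(validation_report,
                   file.path(config$output_dir, "validation.csv"))
  if (nrow(ad_report)) {
    readr::write_csv(ad_report,
                     file.path(config$output_dir, "applicability.csv"))
  }
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       digits = NA, na = "null", pretty = TRUE)

  invisible(list(models = models, validation = validations, ad = ads,
                 foley = foley, summary = summary,
                 output_dir = config$output_dir))
}

#' Refit the twenty published models and compare with the printed values
#'
#' Fits every bundled model specification on the packaged dataset and
#' compares each computed coefficient, standard error, R2, residual sd,
#' integer-rounded F, adjusted R2 and PRESS with the published value under
#' the last-printed-decimal tolerance policy (see [matches_printed()]).
#' The VIF comparison checks the published upper bound.
#'
#' @param tolerance_units Half-width of the match band, in units of the
#'   last printed decimal (default 1.5).
#' @param table Compound table to refit on (default the bundled dataset).
#' @return A tibble with one row per compared quantity: `label`,
#'   `quantity`, `printed`, `computed`, `tolerance`, `pass`. The overall
#'   pass fraction is attached as attribute `"pass_rate"`.
#' @export
reproduce_paper <- function(tolerance_units = 1.5,
                            table = bundled_paper_dataset()) {
  specs <- paper_model_specs()
  ref_stats <- reference_fit_stats()
  ref_coef <- reference_coefficients()
  rows <- list()
  add <- function(label, quantity, printed, computed, pass = NULL) {
    tol <- printed_tolerance(printed, tolerance_units)
    rows[[length(rows) + 1]] <<- tibble(
      label = label, quantity = quantity, printed = as.numeric(printed),
      computed = computed, tolerance = tol,
      pass = pass %||% matches_printed(computed, printed, tolerance_units))
  }
  for (i in seq_len(nrow(ref_stats))) {
    lbl <- ref_stats$label[i]
    m <- fit_mlr(table, specs[[lbl]])
    v <- loo_validate(m)
    add(lbl, "r_squared", ref_stats$r_squared[i], m$r_squared)
    add(lbl, "sd", ref_stats$sd[i], m$sd_resid)
    add(lbl, "f", ref_stats$f[i], round(m$f_stat))
    add(lbl, "adj_r_squared", ref_stats$adj_r_squared[i], m$adj_r_squared)
    add(lbl, "press", ref_stats$press[i], v$press)
    # published VIFs are upper bounds; the bound keeps its printed-decimal
    # tolerance like every other comparison
    add(lbl, "max_vif", ref_stats$max_vif[i], max(v$vif),
        pass = max(v$vif) <= as.numeric(ref_stats$max_vif[i]) +
          printed_tolerance(ref_stats$max_vif[i], tolerance_units))
    rc <- ref_coef[ref_coef$label == lbl, ]
    for (j in seq_len(nrow(rc))) {
      est <- m$coefficients$estimate[m$coefficients$term == rc$term[j]]
      se <- m$coefficients$std_error[m$coefficients$term == rc$term[j]]
      add(lbl, paste0("coef:", rc$term[j]), rc$estimate[j], est)
      add(lbl, paste0("se:", rc$term[j]), rc$std_error[j], se)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "pass_rate") <- mean(out$pass)
  out
}

#' Correlations of micellar retention between eluent compositions
#'
#' Pearson correlation matrix of the per-compound `log10(k)` vectors
#' between every pair of surfactant concentrations in the MLC retention
#' table. High off-diagonal values justify using a single eluent's
#' retention (e.g. `log_k01`) as the lipophilicity descriptor.
#'
#' @param table A [compound_table()] whose compounds all share the same
#'   MLC concentration grid.
#' @return A symmetric correlation matrix with concentrations as dimnames.
#' @export
eluent_correlation_report <- function(table) {
  validate_compound_table(table)
  mlc <- table$retention[table$retention$system == "MLC", ]
  if (!nrow(mlc)) {
    abort("no MLC retention data", class = "mlcqsar_insufficient_data")
  }
  xs <- sort(unique(mlc$x))
  ids <- unique(mlc$compound_id)
  mat <- sapply(xs, function(x0) {
    sub <- mlc[abs(mlc$x - x0) < 1e-12, ]
    if (!setequal(sub$compound_id, ids) || nrow(sub) != length(ids)) {
      abort("compounds measured on mismatched concentration grids",
            class = "mlcqsar_validation_error")
    }
    log10(sub$k[match(ids, sub$compound_id)])
  })
  colnames(mat) <- format(xs)
  stats::cor(mat)
}
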