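# File formats: inventory CSV/JSON, measurement and profile CSVs, YAML
# config, and JSON/Markdown report rendering with a shipped schema.

INVENTORY_COLUMNS <- c("id", "name", "molecular_weight", "charge_class",
                       "hydrophobicity_class", "surfactant",
                       "critical_micelle_concentration", "usage_stage",
                       "usage_concentration", "evidence_codes")

inventory_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r)
    data.frame(id = r$id, name = r$name,
               molecular_weight = r$molecular_weight,
               charge_class = r$charge_class,
               hydrophobicity_class = r$hydrophobicity_class,
               surfactant = r$surfactant,
               critical_micelle_concentration =
                 r$critical_micelle_concentration,
               usage_stage = r$usage_stage,
               usage_concentration = r$usage_concentration,
               evidence_codes = paste(r$evidence_codes, collapse = ";"),
               stringsAsFactors = FALSE)))
}

df_to_inventory <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    pri_record(
      id = r$id, name = r$name, usage_stage = r$usage_stage,
      usage_concentration = r$usage_concentration,
      evidence_codes = strsplit(as.character(r$evidence_codes), ";",
                                fixed = TRUE)[[1]],
      molecular_weight = if ("molecular_weight" %in% names(r))
        r$molecular_weight else NA_real_,
      charge_class = if ("charge_class" %in% names(r)) r$charge_class
        else "unknown",
      hydrophobicity_class = if ("hydrophobicity_class" %in% names(r))
        r$hydrophobicity_class else "unknown",
      surfactant = if ("surfactant" %in% names(r))
        isTRUE(as.logical(r$surfactant)) else FALSE,
      critical_micelle_concentration =
        if ("critical_micelle_concentration" %in% names(r))
          r$critical_micelle_concentration else NA_real_)
  })
}

#' Read / write an impurity inventory
#'
#' CSV (one impurity per row, evidence codes semicolon-delimited in one
#' column) or JSON (array of objects with the same fields, evidence codes as
#' an array), chosen by file extension. Reading validates every record;
#' writing then reading reproduces all fields exactly.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @param records List of [pri_record()]s (for writing).
#' @return `read_inventory()` returns a list of [pri_record()]s.
#' @export
read_inventory <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(c("id", "name", "usage_stage", "usage_concentration",
                         "evidence_codes"), names(df))
    if (length(missing) > 0)
      stop("inventory CSV missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    df_to_inventory(df)
  } else if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(raw, function(r)
      pri_record(id = r$id, name = r$name, usage_stage = r$usage_stage,
                 usage_concentration = r$usage_concentration,
                 evidence_codes = unlist(r$evidence_codes),
                 molecular_weight = r$molecular_weight %||% NA_real_,
                 charge_class = r$charge_class %||% "unknown",
                 hydrophobicity_class = r$hydrophobicity_class %||% "unknown",
                 surfactant = isTRUE(r$surfactant),
                 critical_micelle_concentration =
                   r$critical_micelle_concentration %||% NA_real_))
  } else {
    stop("unsupported inventory format: .", ext, call. = FALSE)
  }
}

#' @rdname read_inventory
#' @export
write_inventory <- function(records, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(inventory_to_df(records), path, row.names = FALSE,
                     na = "")
  } else if (ext == "json") {
    out <- lapply(records, function(r) {
      x <- unclass(r)
      x$evidence_codes <- as.list(x$evidence_codes)
      x[!vapply(x, function(v) length(v) == 1 && is.na(v), logical(1))]
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported inventory format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read / write in-process measurement tables
#'
#' CSV with columns `pri_id`, `test_point`, `concentration` (ug/ml),
#' `is_lod`, `protein_concentration` (mg/ml).
#'
#' @param path CSV file path.
#' @param measurements Data.frame with the columns above.
#' @return `read_measurements()` returns the data.frame.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pri_id", "concentration", "is_lod", "protein_concentration")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("measurements CSV missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$is_lod <- as.logical(df$is_lod)
  df
}

#' @rdname read_measurements
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write toxicity reference tables
#'
#' CSV keyed by `pri_id` with optional columns `noel`, `loel` (mg/kg/day),
#' `ld50` (mg/kg), `ld50_route`, `established_pde` (ug/day) and
#' `severe_toxicity`; empty cells mean "no data".
#'
#' @param path CSV file path.
#' @param tox_map Named list of [toxicity_profile()]s (for writing).
#' @return `read_toxicity()` returns a named list of [toxicity_profile()]s
#'   keyed by impurity id.
#' @export
read_toxicity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"pri_id" %in% names(df))
    stop("toxicity CSV missing column: pri_id", call. = FALSE)
  col <- function(r, nm, default) {
    if (nm %in% names(df)) {
      v <- df[[nm]][r]
      if (is.na(v) || identical(v, "")) default else v
    } else default
  }
  out <- lapply(seq_len(nrow(df)), function(i)
    toxicity_profile(noel = as.numeric(col(i, "noel", NA)),
                     loel = as.numeric(col(i, "loel", NA)),
                     ld50 = as.numeric(col(i, "ld50", NA)),
                     ld50_route = as.character(col(i, "ld50_route", "other")),
                     established_pde =
                       as.numeric(col(i, "established_pde", NA)),
                     severe_toxicity =
                       isTRUE(as.logical(col(i, "severe_toxicity", FALSE)))))
  names(out) <- df$pri_id
  out
}

#' @rdname read_toxicity
#' @export
write_toxicity <- function(tox_map, path) {
  df <- do.call(rbind, lapply(names(tox_map), function(id) {
    t <- tox_map[[id]]
    data.frame(pri_id = id, noel = t$noel, loel = t$loel, ld50 = t$ld50,
               ld50_route = t$ld50_route, established_pde = t$established_pde,
               severe_toxicity = t$severe_toxicity, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write diafiltration profiles
#'
#' CSV with columns `diavolume`, `concentration` and optional `is_lod`;
#' `c0` is taken from the first row (diavolume 0).
#'
#' @param path CSV file path.
#' @param profile A [diafiltration_profile()].
#' @return `read_profile()` returns a [diafiltration_profile()].
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("diavolume", "concentration"), names(df))
  if (length(missing) > 0)
    stop("profile CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  is_lod <- if ("is_lod" %in% names(df)) as.logical(df$is_lod) else FALSE
  diafiltration_profile(c0 = df$concentration[df$diavolume == 0][1],
                        diavolume = df$diavolume,
                        concentration = df$concentration, is_lod = is_lod)
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "diafiltration_profile"))
  utils::write.csv(profile$points, path, row.names = FALSE)
  invisible(path)
}

#' Read an assessment configuration file
#'
#' YAML with any of: `body_weight` (kg), `ttc` (ug/day), `isf_threshold`,
#' `product_dose` (mg), `product_protein_concentration` (mg/ml),
#' `factors` (map f1..f5), `fit_r2_threshold`, `test_point_mode`,
#' `stage_protein_concentrations` (map keyed by usage stage). Unset keys get
#' package defaults.
#'
#' @param path YAML file path.
#' @return List with `context` (a [dose_context()]), `fit_r2_threshold` and
#'   `test_point_mode`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  f <- cfg$factors %||% list()
  factors <- modifying_factors(f1 = f$f1 %||% 1, f2 = f$f2 %||% 10,
                               f3 = f$f3 %||% 1, f4 = f$f4 %||% 1,
                               f5 = f$f5 %||% 1)
  spc <- cfg$stage_protein_concentrations
  if (!is.null(spc)) spc <- unlist(spc)
  ctx <- dose_context(
    product_dose = cfg$product_dose %||%
      stop("config must set product_dose (mg)", call. = FALSE),
    product_protein_concentration = cfg$product_protein_concentration %||%
      stop("config must set product_protein_concentration (mg/ml)",
           call. = FALSE),
    body_weight = cfg$body_weight %||% 50,
    factors = factors, ttc = cfg$ttc %||% 1.5,
    isf_threshold = cfg$isf_threshold %||% NA_real_,
    stage_protein_concentrations = spc)
  list(context = ctx,
       fit_r2_threshold = cfg$fit_r2_threshold %||% 0.95,
       test_point_mode = cfg$test_point_mode %||% "staged")
}

report_to_list <- function(report, seed = NULL) {
  list(
    header = list(tool = "prisafe",
                  version = as.character(utils::packageVersion("prisafe")),
                  seed = seed, config = report$config),
    summary = list(
      n = report$summary$n,
      by_category = as.list(stats::setNames(
        as.integer(report$summary$by_category),
        names(report$summary$by_category))),
      by_disposition = as.list(stats::setNames(
        as.integer(report$summary$by_disposition),
        names(report$summary$by_disposition)))),
    outcomes = report$table,
    testing_plan = report$testing_plan,
    unmatched_measurements = report$unmatched_measurements)
}

#' Render a workflow report
#'
#' JSON (machine-readable; validates against the schema shipped at
#' `system.file("extdata", "report-schema.json", package = "prisafe")`) or
#' Markdown (human-readable, with the category tally and testing plan). The
#' header records tool version, seed and the configuration snapshot so a
#' report is reproducible from its own metadata; no timestamp is written, so
#' identical inputs give byte-identical reports.
#'
#' @param report A `workflow_report` from [run_workflow()].
#' @param format `"json"` or `"markdown"`.
#' @param path Optional output file; when `NULL` the text is returned only.
#' @param seed Optional seed to record in the header.
#' @return The rendered text, invisibly when written to `path`.
#' @export
render_report <- function(report, format = c("json", "markdown"),
                          path = NULL, seed = NULL) {
  stopifnot(inherits(report, "workflow_report"))
  format <- match.arg(format)
  if (format == "json") {
    txt <- jsonlite::toJSON(report_to_list(report, seed), auto_unbox = TRUE,
                            digits = NA, pretty = TRUE, na = "null",
                            null = "null")
  } else {
    s <- report$summary
    lines <- c(
      "# LMW PRI safety risk assessment report", "",
      sprintf("- impurities assessed: %d", s$n),
      sprintf("- tool version: %s", utils::packageVersion("prisafe")), "",
      "## Category tally", "",
      "| Category | Count |", "|---|---|",
      sprintf("| %s | %d |", names(s$by_category),
              as.integer(s$by_category)), "",
      "## Dispositions", "",
      "| Disposition | Count |", "|---|---|",
      sprintf("| %s | %d |", names(s$by_disposition),
              as.integer(s$by_disposition)), "")
    if (nrow(report$testing_plan) > 0) {
      lines <- c(lines, "## Testing plan", "",
                 "| PRI | Test point | Assay LOD (ug/ml) |", "|---|---|---|",
                 sprintf("| %s | %s | %.4g |", report$testing_plan$pri_id,
                         report$testing_plan$test_point,
                         report$testing_plan$assay_lod), "")
    }
    if (nrow(report$table) > 0) {
      lines <- c(lines, "## Outcomes", "",
                 "| PRI | Category | Stage | Disposition | Dose (ug) | Limit (ug/day) | Basis |",
                 "|---|---|---|---|---|---|---|",
                 sprintf("| %s | %s | %s | %s | %.4g | %.4g | %s |",
                         report$table$pri_id, report$table$category,
                         report$table$stage, report$table$disposition,
                         report$table$pri_dose, report$table$limit,
                         ifelse(is.na(report$table$limit_type), "-",
                                report$table$limit_type)), "")
    }
    txt <- paste(lines, collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Structurally validate a JSON report against the shipped schema
#'
#' A lightweight structural checker (required keys and basic types) written
#' against the JSON Schema document shipped in `inst/extdata`; it covers the
#' fields downstream consumers rely on.
#'
#' @param path Path to a JSON report written by [render_report()].
#' @return `TRUE` invisibly on success; errors with the first violation
#'   otherwise.
#' @export
validate_report_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need_top <- c("header", "summary", "outcomes", "testing_plan")
  miss <- setdiff(need_top, names(x))
  if (length(miss) > 0)
    stop("report missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.list(x$header) || is.null(x$header$version))
    stop("report header must carry a version", call. = FALSE)
  s <- x$summary
  if (is.null(s$n) || !is.numeric(s$n))
    stop("summary.n must be a number", call. = FALSE)
  for (k in c("by_category", "by_disposition"))
    if (!is.list(s[[k]]) && !is.numeric(unlist(s[[k]])))
      stop("summary.", k, " must map labels to counts", call. = FALSE)
  counts <- sum(unlist(s$by_category))
  if (counts != s$n)
    stop("category counts do not sum to inventory size", call. = FALSE)
  invisible(TRUE)
}
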