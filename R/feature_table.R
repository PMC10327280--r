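# Feature tables: one row per subject, metadata columns first, then one
# numeric column per morphometric feature. The table is the exchange object
# shared by every other module.

FT_META <- c("subject_id", "cohort", "diagnosis", "sex", "age")
DIAGNOSIS_LEVELS <- c("HC", "EM", "CM")
SEX_LEVELS <- c("F", "M", "unknown")
MODALITIES <- c("thickness", "area", "volume")

#' Construct a feature table
#'
#' A feature table is a tibble with the metadata columns `subject_id`,
#' `cohort`, `diagnosis` (one of `HC`, `EM`, `CM`), `sex` (`F`, `M`,
#' `unknown`), `age` (years, may be `NA`), followed by one numeric column per
#' feature. Feature columns are expected to follow the
#' `<hemisphere>_<region>_<modality>` naming convention used by cortical
#' morphometric exports (e.g. `lh_precentral_thickness`); the modality is the
#' final underscore-separated token.
#'
#' @param x A data frame containing the metadata and feature columns.
#' @param feature_cols Character vector naming the feature columns. Defaults
#'   to every non-metadata column.
#' @param validate Abort when validation finds an error-severity issue.
#' @return A tibble of class `feature_table` whose `feature_names` attribute
#'   records the feature column order.
#' @export
feature_table <- function(x, feature_cols = NULL, validate = TRUE) {
  x <- as_tibble(x)
  missing_meta <- setdiff(c("subject_id", "cohort", "diagnosis"), names(x))
  if (length(missing_meta) > 0) {
    stop_hc(
      paste0("missing mandatory column(s): ", paste(missing_meta, collapse = ", ")),
      "healthycore_schema_error"
    )
  }
  if (!"sex" %in% names(x)) x$sex <- "unknown"
  if (!"age" %in% names(x)) x$age <- NA_real_
  x$sex[is.na(x$sex)] <- "unknown"
  feature_cols <- feature_cols %||% setdiff(names(x), FT_META)
  unknown <- setdiff(feature_cols, names(x))
  if (length(unknown) > 0) {
    stop_hc(
      paste0("feature column(s) not present: ", paste(head(unknown, 5), collapse = ", ")),
      "healthycore_schema_error"
    )
  }
  x <- x[, c(FT_META, feature_cols)]
  x$subject_id <- as.character(x$subject_id)
  x$cohort <- as.character(x$cohort)
  x$diagnosis <- as.character(x$diagnosis)
  x$sex <- as.character(x$sex)
  x$age <- as.numeric(x$age)
  out <- structure(x, feature_names = feature_cols,
                   class = c("feature_table", class(x)))
  if (validate) {
    report <- validate_feature_table(out)
    if (!report$passed) {
      bad <- dplyr::filter(report$issues, .data$severity == "error")
      stop_hc(
        paste0("invalid feature table: ",
               paste(head(bad$message, 5), collapse = "; ")),
        "healthycore_integrity_error", report = report
      )
    }
  }
  out
}

#' Validate a feature table
#'
#' Checks the invariants a feature table must satisfy: unique subject ids,
#' legal diagnosis codes, finite numeric feature values. Missing age or an
#' unrecognized sex code is reported as a warning-severity issue (the
#' modelling functions only require complete feature matrices); a missing or
#' non-finite feature value is an error.
#'
#' @param x A data frame shaped like a feature table.
#' @return A list with `passed` (logical) and `issues`, a tibble with columns
#'   `row` (1-based data row, `NA` for table-level issues), `column`, `code`,
#'   `severity` (`"error"` or `"warning"`) and `message`.
#' @export
validate_feature_table <- function(x) {
  issues <- list()
  add <- function(row, column, code, severity, message) {
    issues[[length(issues) + 1]] <<- tibble(
      row = as.integer(row), column = column, code = code,
      severity = severity, message = message
    )
  }
  dup <- which(duplicated(x$subject_id))
  for (i in dup) {
    add(i, "subject_id", "duplicate_id", "error",
        sprintf("duplicate subject_id '%s' at row %d", x$subject_id[i], i))
  }
  bad_dx <- which(!x$diagnosis %in% DIAGNOSIS_LEVELS)
  for (i in bad_dx) {
    add(i, "diagnosis", "bad_diagnosis", "error",
        sprintf("diagnosis '%s' at row %d is not one of %s",
                x$diagnosis[i], i, paste(DIAGNOSIS_LEVELS, collapse = "/")))
  }
  bad_sex <- which(!x$sex %in% SEX_LEVELS)
  for (i in bad_sex) {
    add(i, "sex", "bad_sex", "warning",
        sprintf("sex '%s' at row %d is not F/M/unknown", x$sex[i], i))
  }
  for (i in which(!is.na(x$age) & x$age <= 0)) {
    add(i, "age", "bad_age", "warning", sprintf("non-positive age at row %d", i))
  }
  for (f in feature_names(x)) {
    v <- x[[f]]
    if (!is.numeric(v)) {
      add(NA, f, "non_numeric", "error",
          sprintf("feature column '%s' is not numeric", f))
      next
    }
    for (i in which(!is.finite(v))) {
      add(i, f, "non_finite", "error",
          sprintf("non-finite value in feature '%s' at row %d", f, i))
    }
  }
  issues <- if (length(issues) == 0) {
    tibble(row = integer(), column = character(), code = character(),
           severity = character(), message = character())
  } else {
    bind_rows(issues)
  }
  list(passed = !any(issues$severity == "error"), issues = issues)
}

#' Feature column names of a table
#'
#' @param x A feature table (or any data frame using the standard metadata
#'   columns).
#' @return Character vector of feature column names, in stored order.
#' @export
feature_names <- function(x) {
  attr(x, "feature_names") %||% setdiff(names(x), FT_META)
}

#' Extract the numeric feature matrix
#'
#' @param x A feature table.
#' @return A numeric matrix, one row per subject (rownames = subject ids),
#'   one column per feature.
#' @export
feature_matrix <- function(x) {
  m <- as.matrix(x[, feature_names(x), drop = FALSE])
  rownames(m) <- x$subject_id
  m
}

#' Modality tag of each feature name
#'
#' The modality is the final underscore-separated token of the feature name;
#' names without a recognized tag get `NA`.
#'
#' @param features Character vector of feature names.
#' @return Character vector of modalities (`thickness`, `area`, `volume`).
#' @export
feature_modality <- function(features) {
  tag <- sub(".*_", "", features)
  ifelse(tag %in% MODALITIES, tag, NA_character_)
}

#' Read a feature table from CSV/TSV
#'
#' The delimiter is auto-detected from the extension (`.tsv`/`.txt` = tab)
#' unless given. An optional schema maps file column names onto the standard
#' roles, e.g. `list(subject_id = "ID", cohort = "site")`; a path to a
#' YAML/JSON file with the same structure is also accepted. Unmapped
#' non-metadata columns are taken as features in file order.
#'
#' @param path File path.
#' @param schema Named list (or YAML/JSON file path) mapping roles
#'   (`subject_id`, `cohort`, `diagnosis`, `sex`, `age`, optionally
#'   `features`) to file column names.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, schema = NULL, delim = NULL) {
  if (!file.exists(path)) {
    stop_hc(paste0("file not found: ", path), "healthycore_io_error")
  }
  if (is.character(schema) && length(schema) == 1) schema <- read_schema(schema)
  delim <- delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(schema)) {
    for (role in intersect(names(schema), FT_META)) {
      col <- schema[[role]]
      if (!col %in% names(raw)) {
        stop_hc(sprintf("schema maps role '%s' to missing column '%s'", role, col),
                "healthycore_schema_error")
      }
      names(raw)[names(raw) == col] <- role
    }
  }
  missing_meta <- setdiff(c("subject_id", "cohort", "diagnosis"), names(raw))
  if (length(missing_meta) > 0) {
    stop_hc(
      paste0("missing mandatory column(s): ", paste(missing_meta, collapse = ", "),
             if (is.null(schema)) " (pass a schema to map differently named columns)" else ""),
      "healthycore_schema_error"
    )
  }
  feature_cols <- schema$features %||% setdiff(names(raw), FT_META)
  if (nrow(raw) == 0) {
    for (f in feature_cols) raw[[f]] <- as.numeric(raw[[f]])
  }
  for (f in feature_cols) {
    if (!is.numeric(raw[[f]])) {
      bad <- suppressWarnings(which(is.na(as.numeric(raw[[f]])) & !is.na(raw[[f]])))
      stop_hc(
        sprintf("non-numeric value in feature column '%s'%s", f,
                if (length(bad) > 0) sprintf(" at row %d", bad[1]) else ""),
        "healthycore_parse_error"
      )
    }
  }
  feature_table(raw, feature_cols = feature_cols)
}

read_schema <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Write a feature table to CSV/TSV
#'
#' Metadata columns are written first, then features in stored order, at full
#' double precision so that write-then-read round trips.
#'
#' @param x A feature table.
#' @param path Output path; `.tsv`/`.txt` selects tab delimiting.
#' @return `x`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(as_tibble(as.data.frame(x)), path, delim = delim)
  invisible(x)
}

#' Filter rows of a feature table
#'
#' Filters by the conjunction of the supplied criteria. When `ids` is given
#' the rows are returned in the requested order.
#'
#' @param x A feature table.
#' @param cohort,diagnosis Optional labels to keep.
#' @param ids Optional subject ids to keep (request order preserved).
#' @return A feature table with the same feature columns.
#' @export
subset_rows <- function(x, cohort = NULL, diagnosis = NULL, ids = NULL) {
  out <- x
  if (!is.null(cohort)) {
    missing <- setdiff(cohort, unique(x$cohort))
    if (length(missing) > 0) {
      stop_hc(paste0("unknown cohort label(s): ", paste(missing, collapse = ", ")),
              "healthycore_lookup_error")
    }
    out <- out[out$cohort %in% cohort, ]
  }
  if (!is.null(diagnosis)) {
    missing <- setdiff(diagnosis, DIAGNOSIS_LEVELS)
    if (length(missing) > 0) {
      stop_hc(paste0("unknown diagnosis label(s): ", paste(missing, collapse = ", ")),
              "healthycore_lookup_error")
    }
    out <- out[out$diagnosis %in% diagnosis, ]
  }
  if (!is.null(ids)) {
    missing <- setdiff(ids, out$subject_id)
    if (length(missing) > 0) {
      stop_hc(paste0("unknown subject id(s): ", paste(head(missing, 5), collapse = ", ")),
              "healthycore_lookup_error")
    }
    out <- out[match(ids, out$subject_id), ]
  }
  restore_feature_table(out, x)
}

restore_feature_table <- function(x, template) {
  x <- as_tibble(x)
  class(x) <- setdiff(class(x), "feature_table")
  structure(x, feature_names = feature_names(template),
            class = c("feature_table", class(x)))
}

#' @export
print.feature_table <- function(x, ...) {
  nf <- length(feature_names(x))
  cat(sprintf("# feature_table: %d subjects x %d features (%s)\n",
              nrow(x), nf,
              paste(sprintf("%s=%d", names(table(x$cohort)), table(x$cohort)),
                    collapse = ", ")))
  NextMethod()
}
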