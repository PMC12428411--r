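#' Write a cohort to plain-text files
#'
#' Emits `patients.csv`, `lesions.csv` and `registry.json` (plus
#' `truth.json` when the cohort carries generator truth) into `dir`.
#' Missing feature values become empty CSV cells; they are never imputed
#' at I/O time.
#'
#' @param cohort A [prrt_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stop_if_not(inherits(cohort, "prrt_cohort"), "`cohort` must be a prrt_cohort.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), na = "")
  readr::write_csv(cohort$lesions, file.path(dir, "lesions.csv"), na = "")
  reg <- cohort$registry
  reg_list <- setNames(
    pmap(reg, function(name, group, dtype, level, missing_rate, planted, effect, ...) {
      list(group = group, dtype = dtype, level = level,
           missing_rate = missing_rate, planted = planted, effect = effect)
    }),
    reg$name
  )
  jsonlite::write_json(reg_list, file.path(dir, "registry.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a cohort from plain-text files
#'
#' Inverse of [write_cohort()]: reads the two CSV tables and the JSON
#' registry, re-derives column types from the registry (binary features
#' as integer 0/1, numeric as double), keeps empty cells as explicit
#' `NA`, and re-validates all cohort invariants.
#'
#' @param dir Directory holding `patients.csv`, `lesions.csv`,
#'   `registry.json` (and optionally `truth.json`).
#' @return A [prrt_cohort()].
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, c("patients.csv", "lesions.csv", "registry.json"))
  missing <- paths[!file.exists(paths)]
  stop_if_not(length(missing) == 0,
              paste("Missing cohort file(s):", paste(missing, collapse = ", ")))

  reg_list <- jsonlite::read_json(paths[3])
  registry <- tibble(
    name = names(reg_list),
    group = map_chr(reg_list, "group"),
    dtype = map_chr(reg_list, "dtype"),
    level = map_chr(reg_list, "level"),
    missing_rate = map_dbl(reg_list, "missing_rate"),
    planted = map_lgl(reg_list, ~ isTRUE(.x$planted)),
    effect = map_dbl(reg_list, ~ .x$effect %||% 0)
  )

  feat_cols <- function(level) {
    feats <- registry[registry$level == level, ]
    setNames(
      lapply(feats$dtype,
             function(d) if (d == "binary") readr::col_integer() else readr::col_double()),
      feats$name
    )
  }
  pat_types <- do.call(readr::cols, c(
    list(patient_id = readr::col_character(), eligible = readr::col_logical()),
    feat_cols("patient")
  ))
  les_types <- do.call(readr::cols, c(
    list(patient_id = readr::col_character(), lesion_id = readr::col_character(),
         site = readr::col_character(), ratio_liver = readr::col_double(),
         ratio_spleen = readr::col_double(), krenning = readr::col_integer(),
         pro_prrt = readr::col_logical()),
    feat_cols("lesion")
  ))

  patients <- readr::read_csv(paths[1], col_types = pat_types, na = "")
  lesions <- readr::read_csv(paths[2], col_types = les_types, na = "")
  for (tab in list(patients = patients, lesions = lesions)) {
    probs <- readr::problems(tab)
    if (nrow(probs) > 0) {
      rlang::abort(
        sprintf("Malformed cohort CSV: row %d, column %d (%s).",
                probs$row[1], probs$col[1], probs$expected[1]),
        class = "prrtselect_parse_error"
      )
    }
  }

  unknown_p <- setdiff(names(patients), c("patient_id", "eligible",
                                          registry$name[registry$level == "patient"]))
  unknown_l <- setdiff(names(lesions),
                       c("patient_id", "lesion_id", "site", "ratio_liver",
                         "ratio_spleen", "krenning", "pro_prrt",
                         registry$name[registry$level == "lesion"]))
  stop_if_not(length(unknown_p) == 0,
              paste("Unknown patient column(s):", paste(unknown_p, collapse = ", ")))
  stop_if_not(length(unknown_l) == 0,
              paste("Unknown lesion column(s):", paste(unknown_l, collapse = ", ")))

  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                            simplifyVector = TRUE)
  prrt_cohort(patients, lesions, registry, truth = truth)
}
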