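#' Construct a two-level cohort object
#'
#' A `prrt_cohort` bundles the two tables of the study design — one row
#' per patient and one row per lesion — together with the feature
#' registry that assigns every feature a variable group, a dtype and a
#' level. Lesion rows reference patient rows by `patient_id`; derived
#' outcome columns (`krenning`, `pro_prrt`, `eligible`) are validated
#' against the uptake ratios and the least-active-lesion rule.
#'
#' @param patients Tibble with columns `patient_id`, `eligible`, then one
#'   column per patient-level feature in `registry`.
#' @param lesions Tibble with columns `patient_id`, `lesion_id`, `site`,
#'   `ratio_liver`, `ratio_spleen`, `krenning`, `pro_prrt`, then one
#'   column per lesion-level feature in `registry`.
#' @param registry Feature registry tibble: `name`, `group`
#'   (one of [variable_groups()]), `dtype` (`"binary"`/`"numeric"`),
#'   `level` (`"patient"`/`"lesion"`), `missing_rate` in \[0,1\], and
#'   optionally `planted`/`effect` (filled by the synthetic generator).
#' @param truth Optional list recording planted effects and the seed
#'   (kept by [generate_cohort()] for recovery scoring).
#' @param thresholds Krenning thresholds the scores must satisfy.
#' @return An object of class `prrt_cohort`.
#' @export
prrt_cohort <- function(patients, lesions, registry, truth = NULL,
                        thresholds = krenning_thresholds()) {
  registry <- as_tibble(registry)
  stop_if_not(all(c("name", "group", "dtype", "level", "missing_rate") %in%
                    names(registry)),
              "Registry needs columns name, group, dtype, level, missing_rate.")
  stop_if_not(!anyDuplicated(registry$name), "Feature names must be unique.")
  stop_if_not(all(registry$group %in% variable_groups()),
              "Every feature must belong to one of the four variable groups.")
  stop_if_not(all(registry$dtype %in% c("binary", "numeric")),
              "Feature dtype must be 'binary' or 'numeric'.")
  stop_if_not(all(registry$level %in% c("patient", "lesion")),
              "Feature level must be 'patient' or 'lesion'.")
  stop_if_not(all(registry$missing_rate >= 0 & registry$missing_rate <= 1),
              "missing_rate must lie in [0, 1].")
  if (!"planted" %in% names(registry)) registry$planted <- FALSE
  if (!"effect" %in% names(registry)) registry$effect <- 0

  patients <- as_tibble(patients)
  lesions <- as_tibble(lesions)
  pat_feats <- registry$name[registry$level == "patient"]
  les_feats <- registry$name[registry$level == "lesion"]
  miss_p <- setdiff(pat_feats, names(patients))
  miss_l <- setdiff(les_feats, names(lesions))
  stop_if_not(length(miss_p) == 0,
              paste("Patient table lacks registry feature(s):",
                    paste(utils::head(miss_p, 5), collapse = ", ")))
  stop_if_not(length(miss_l) == 0,
              paste("Lesion table lacks registry feature(s):",
                    paste(utils::head(miss_l, 5), collapse = ", ")))

  orphan <- setdiff(lesions$patient_id, patients$patient_id)
  if (length(orphan) > 0) {
    bad <- lesions$lesion_id[lesions$patient_id %in% orphan]
    rlang::abort(paste0("Lesion(s) reference unknown patient_id: ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 class = "prrtselect_foreign_key_error")
  }
  stop_if_not(all(patients$patient_id %in% lesions$patient_id),
              "Every patient must have at least one lesion.")

  # outcome consistency: scores follow the ratios, flags follow the scores
  expect_k <- krenning_from_ratios(lesions$ratio_liver, lesions$ratio_spleen,
                                   thresholds)
  stop_if_not(all(lesions$krenning == expect_k),
              "Lesion `krenning` inconsistent with uptake ratios under the thresholds.")
  stop_if_not(all(lesions$pro_prrt == lesion_pro_prrt(lesions$krenning)),
              "Lesion `pro_prrt` must equal (krenning >= 3).")
  elig <- lesions |>
    group_by(.data$patient_id) |>
    summarise(eligible = all(.data$pro_prrt), .groups = "drop")
  chk <- left_join(patients["patient_id"], elig, by = "patient_id")
  stop_if_not(all(patients$eligible == chk$eligible),
              "Patient `eligible` must follow the least-active-lesion rule.")

  structure(
    list(patients = patients, lesions = lesions, registry = registry,
         truth = truth, thresholds = thresholds),
    class = "prrt_cohort"
  )
}

#' @export
print.prrt_cohort <- function(x, ...) {
  cat("<prrt_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$lesions), " lesions\n", sep = "")
  cat("  features: ", sum(x$registry$level == "patient"), " patient-level, ",
      sum(x$registry$level == "lesion"), " lesion-level (",
      paste(names(table(x$registry$group)), table(x$registry$group),
            sep = ":", collapse = ", "), ")\n", sep = "")
  cat("  eligible: ", sum(x$patients$eligible), "/", nrow(x$patients),
      " patients; ProPRRT lesions: ", sum(x$lesions$pro_prrt), "/",
      nrow(x$lesions), "\n", sep = "")
  invisible(x)
}

#' Reference cohort composition
#'
#' Published composition of the single-center metastatic-NEN cohort this
#' package's synthetic generator emulates: 65 patients (21 PRRT-suitable,
#' 44 not) with 392 confirmed lesions (47 primary tumors, 345 metastases),
#' of which 197 scored Krenning 3--4, 35 Krenning 2 and 160 Krenning 0--1.
#'
#' @return A tibble of named counts.
#' @export
reference_cohort_counts <- function() {
  tibble(
    n_patients = 65L,
    n_eligible = 21L,
    n_not_eligible = 44L,
    n_lesions = 392L,
    n_primary = 47L,
    n_metastatic = 345L,
    n_krenning_34 = 197L,
    n_krenning_2 = 35L,
    n_krenning_01 = 160L,
    n_net = 51L,
    n_nec = 14L
  )
}

#' Descriptive summary of a cohort
#'
#' Counts patients, lesions, Krenning bins, eligibility split and
#' per-site lesion composition.
#'
#' @param cohort A [prrt_cohort()].
#' @return A list of tibbles: `totals`, `krenning`, `sites`.
#' @export
summarize_cohort <- function(cohort) {
  stop_if_not(inherits(cohort, "prrt_cohort"), "`cohort` must be a prrt_cohort.")
  bins <- table(krenning_bin(cohort$lesions$krenning))
  list(
    totals = tibble(
      n_patients = nrow(cohort$patients),
      n_lesions = nrow(cohort$lesions),
      n_eligible = sum(cohort$patients$eligible),
      n_not_eligible = sum(!cohort$patients$eligible),
      n_pro_prrt_lesions = sum(cohort$lesions$pro_prrt),
      min_lesions_per_patient = min(table(cohort$lesions$patient_id))
    ),
    krenning = tibble(bin = names(bins), n = as.integer(bins)),
    sites = count(cohort$lesions, .data$site, name = "n")
  )
}
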