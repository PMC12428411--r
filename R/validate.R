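#' Confirm selected features with classical nonparametric tests
#'
#' The machine-learning selection is checked against standard
#' statistics, mirroring the study's routing:
#'
#' * **Lesion level** — the continuous outcome is the lesion-to-liver
#'   uptake ratio. Binary features split the lesions into two groups
#'   compared by Mann-Whitney U; few-valued features (<= `max_kw_levels`
#'   distinct observed values) use Kruskal-Wallis across their levels;
#'   other numeric features are dichotomized at a clinical cut-off
#'   (`cutoffs`, falling back to the observed median) and compared by
#'   Mann-Whitney.
#' * **Patient level** — the binary outcome is PRRT eligibility; each
#'   feature (dichotomized the same way when numeric) forms a 2 x 2
#'   table tested by chi-square.
#'
#' Patient-level features are carried onto lesions through
#' `patient_id`. Missing values are excluded pairwise with group sizes
#' reported; features with fewer than two observed levels are skipped
#' with a warning. Raw p-values are compared to `alpha` (no
#' multiple-testing correction, matching the study's rule) unless
#' `adjust = "BH"`.
#'
#' @param cohort A [prrt_cohort()].
#' @param features Character vector of feature names to test (e.g. a
#'   consensus list).
#' @param level `"lesion"`, `"patient"`, or `"both"` (default).
#' @param alpha Significance threshold (default 0.05).
#' @param cutoffs Named numeric vector of dichotomization cut-offs for
#'   numeric features (default: age-style cut at 55 for a feature named
#'   `age`, plus the generator's marker reference limits).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg.
#' @param max_kw_levels Numeric features with at most this many distinct
#'   observed values are treated as ordered categories and tested by
#'   Kruskal-Wallis at lesion level (default 4).
#' @return Tibble: `feature`, `level`, `test`, `statistic`, `p_value`,
#'   `significant`, `n_group_1`, `n_group_2`.
#' @export
validate_features <- function(cohort, features,
                              level = c("both", "lesion", "patient"),
                              alpha = 0.05, cutoffs = default_cutoffs(),
                              adjust = c("none", "BH"), max_kw_levels = 4) {
  level <- match.arg(level)
  adjust <- match.arg(adjust)
  stop_if_not(inherits(cohort, "prrt_cohort"), "`cohort` must be a prrt_cohort.")
  reg <- cohort$registry
  unknown <- setdiff(features, reg$name)
  stop_if_not(length(unknown) == 0,
              paste("Feature(s) not in the cohort:", paste(unknown, collapse = ", ")))

  levels_run <- if (level == "both") c("lesion", "patient") else level
  out <- list()
  for (lvl in levels_run) {
    for (f in features) {
      out[[paste(lvl, f)]] <- validate_one(cohort, f, lvl, cutoffs,
                                           max_kw_levels)
    }
  }
  res <- list_rbind(out[!vapply(out, is.null, TRUE)])
  if (nrow(res) == 0) return(res)
  if (adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
  }
  res$significant <- res$p_value < alpha
  res
}

#' Default dichotomization cut-offs
#'
#' Clinical cut-points used when a numeric feature must be split into
#' two groups: age at 55 years and the conventional upper reference
#' limits of the serum markers produced by the generator.
#'
#' @return Named numeric vector.
#' @export
default_cutoffs <- function() {
  c(age = 55, cga_serum = 100, nse = 16.3, cea = 5, ca19_9 = 37, afp = 10,
    ki67 = 3, lesion_size_mm = 20)
}

# Route one feature to its test; returns NULL when skipped.
validate_one <- function(cohort, f, lvl, cutoffs, max_kw_levels) {
  reg <- cohort$registry
  f_level <- reg$level[reg$name == f]
  f_dtype <- reg$dtype[reg$name == f]

  if (lvl == "lesion") {
    frame <- if (f_level == "patient") {
      left_join(cohort$lesions[c("patient_id", "ratio_liver")],
                cohort$patients[c("patient_id", f)], by = "patient_id")
    } else {
      cohort$lesions[c("ratio_liver", f)]
    }
    vals <- frame[[f]]
    y <- frame$ratio_liver
    keep <- !is.na(vals) & !is.na(y)
    vals <- vals[keep]
    y <- y[keep]
    n_levels <- length(unique(vals))
    if (n_levels < 2) {
      rlang::warn(sprintf("Feature '%s' has < 2 observed levels at lesion level; skipped.", f))
      return(NULL)
    }
    if (f_dtype == "binary") {
      r <- mann_whitney_u(y[vals == 1], y[vals == 0])
      return(tibble(feature = f, level = lvl, test = "mann_whitney",
                    statistic = r$statistic, p_value = r$p_value,
                    n_group_1 = r$n_a, n_group_2 = r$n_b))
    }
    if (n_levels <= max_kw_levels) {
      r <- kruskal_wallis(y, vals)
      return(tibble(feature = f, level = lvl, test = "kruskal_wallis",
                    statistic = r$statistic, p_value = r$p_value,
                    n_group_1 = r$n_total, n_group_2 = NA_integer_))
    }
    cut <- if (f %in% names(cutoffs)) cutoffs[[f]] else median(vals)
    hi <- vals > cut
    if (length(unique(hi)) < 2) {
      rlang::warn(sprintf("Feature '%s' is one-sided at its cut-off; skipped.", f))
      return(NULL)
    }
    r <- mann_whitney_u(y[hi], y[!hi])
    return(tibble(feature = f, level = lvl, test = "mann_whitney",
                  statistic = r$statistic, p_value = r$p_value,
                  n_group_1 = r$n_a, n_group_2 = r$n_b))
  }

  # patient level: chi-square of eligibility against the dichotomized feature
  if (f_level == "lesion") {
    # summarize a lesion feature to its patient mean before dichotomizing
    agg <- cohort$lesions |>
      group_by(.data$patient_id) |>
      summarise(value = mean(.data[[f]], na.rm = TRUE), .groups = "drop")
    frame <- left_join(cohort$patients[c("patient_id", "eligible")], agg,
                       by = "patient_id")
    vals <- frame$value
  } else {
    vals <- cohort$patients[[f]]
  }
  elig <- cohort$patients$eligible
  keep <- !is.na(vals) & is.finite(vals) & !is.na(elig)
  vals <- vals[keep]
  elig <- elig[keep]
  if (length(unique(vals)) < 2) {
    rlang::warn(sprintf("Feature '%s' has < 2 observed levels at patient level; skipped.", f))
    return(NULL)
  }
  if (f_dtype != "binary") {
    cut <- if (f %in% names(cutoffs)) cutoffs[[f]] else median(vals)
    vals <- as.integer(vals > cut)
    if (length(unique(vals)) < 2) {
      rlang::warn(sprintf("Feature '%s' is one-sided at its cut-off; skipped.", f))
      return(NULL)
    }
  }
  tab <- table(factor(vals, levels = c(0, 1)),
               factor(elig, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::warn(sprintf("Feature '%s': degenerate 2x2 margin; skipped.", f))
    return(NULL)
  }
  r <- suppressWarnings(chi_square_test(as.matrix(tab)))
  tibble(feature = f, level = lvl, test = "chi_square",
         statistic = r$statistic, p_value = r$p_value,
         n_group_1 = sum(vals == 0), n_group_2 = sum(vals == 1))
}
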