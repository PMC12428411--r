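#' Krenning score from lesion-to-reference uptake ratios
#'
#' Grades lesion radiotracer uptake on the semiquantitative 0--4 Krenning
#' scale from the lesion-to-liver and lesion-to-spleen activity ratios
#' measured on somatostatin-receptor SPECT/CT. Uptake above the spleen is
#' grade 4, above the liver grade 3, comparable to the liver (within
#' `tol`) grade 2, faint-but-visible uptake grade 1, and background grade 0.
#'
#' Ties at band edges resolve upward (strict `>` at upper boundaries,
#' `>=` at the lower edge of the grade-2 band), so the score is a
#' deterministic, monotone non-decreasing function of each ratio.
#'
#' @param ratio_liver,ratio_spleen Non-negative numeric vectors: lesion
#'   activity divided by reference-organ activity. Recycled to a common
#'   length.
#' @param thresholds Scoring configuration from [krenning_thresholds()].
#' @return Integer vector of scores in `0:4`.
#' @examples
#' krenning_from_ratios(c(0, 0.5, 1.0, 1.4, 1.6), c(0, 0.3, 0.6, 0.9, 1.2))
#' @seealso [lesion_pro_prrt()], [patient_eligibility()]
#' @export
krenning_from_ratios <- function(ratio_liver, ratio_spleen,
                                 thresholds = krenning_thresholds()) {
  check_thresholds(thresholds)
  stop_if_not(is.numeric(ratio_liver) && is.numeric(ratio_spleen),
              "Uptake ratios must be numeric.")
  n <- max(length(ratio_liver), length(ratio_spleen))
  ratio_liver <- rep_len(ratio_liver, n)
  ratio_spleen <- rep_len(ratio_spleen, n)
  bad <- !is.na(ratio_liver) & ratio_liver < 0 |
    !is.na(ratio_spleen) & ratio_spleen < 0
  stop_if_not(!any(bad), "Uptake ratios must be non-negative.")

  tol <- thresholds$tol
  bg <- thresholds$background_cut
  score <- integer(n)
  score[ratio_liver > bg] <- 1L
  score[ratio_liver >= 1 - tol] <- 2L
  score[ratio_liver > 1 + tol] <- 3L
  score[ratio_spleen > 1] <- 4L
  score[is.na(ratio_liver) | is.na(ratio_spleen)] <- NA_integer_
  score
}

#' Krenning scoring thresholds
#'
#' The field's prose convention is qualitative ("uptake higher than the
#' liver", "moderate uptake"); these thresholds make it operational:
#' the grade-2 band is a liver ratio within `1 +/- tol`, grade 1 starts
#' above `background_cut`, and grade 4 requires a spleen ratio above 1.
#'
#' @param tol Half-width of the grade-2 "comparable to liver" band
#'   (default 0.1).
#' @param background_cut Liver-ratio floor separating grade 1 from grade 0
#'   (default 0.2; a declared convention, not a published value).
#' @return A list with class `krenning_thresholds`.
#' @export
krenning_thresholds <- function(tol = 0.1, background_cut = 0.2) {
  out <- list(tol = tol, background_cut = background_cut)
  class(out) <- "krenning_thresholds"
  check_thresholds(out)
  out
}

check_thresholds <- function(x) {
  stop_if_not(
    is.list(x) && is.numeric(x$tol) && is.numeric(x$background_cut) &&
      length(x$tol) == 1L && length(x$background_cut) == 1L &&
      x$tol > 0 && x$tol < 1 &&
      x$background_cut >= 0 && x$background_cut < 1 - x$tol,
    "Malformed Krenning thresholds: need 0 <= background_cut < 1 - tol and 0 < tol < 1."
  )
}

#' Per-lesion PRRT suitability from the Krenning score
#'
#' A lesion supports peptide receptor radionuclide therapy (the "ProPRRT"
#' label) when its uptake exceeds the liver, i.e. Krenning 3--4.
#'
#' @param krenning Integer vector of Krenning scores in `0:4`.
#' @return Logical vector.
#' @export
lesion_pro_prrt <- function(krenning) {
  stop_if_not(
    is.numeric(krenning) && all(is.na(krenning) | (krenning %in% 0:4)),
    "Krenning scores must be integers in 0..4."
  )
  krenning >= 3L
}

#' Patient-level PRRT eligibility via the least active lesion
#'
#' A patient is PRRT-suitable only when every lesion — in particular the
#' least active one — still shows uptake above the liver (Krenning >= 3).
#' Equivalent to the conjunction of [lesion_pro_prrt()] over the patient's
#' lesions.
#'
#' @param krenning Non-empty integer vector of one patient's lesion scores.
#' @return Single logical.
#' @examples
#' patient_eligibility(c(4, 3, 3)) # TRUE
#' patient_eligibility(c(4, 4, 1)) # FALSE: the least active lesion rules
#' @export
patient_eligibility <- function(krenning) {
  stop_if_not(length(krenning) >= 1L, "A patient must have at least one lesion.")
  flags <- lesion_pro_prrt(krenning)
  stop_if_not(!anyNA(flags), "Krenning scores must not be missing.")
  all(flags)
}

#' Collapse Krenning scores to the three reporting bins
#'
#' @param krenning Integer vector of scores in `0:4`.
#' @return Factor with levels `"0-1"`, `"2"`, `"3-4"`.
#' @export
krenning_bin <- function(krenning) {
  stop_if_not(
    is.numeric(krenning) && all(is.na(krenning) | (krenning %in% 0:4)),
    "Krenning scores must be integers in 0..4."
  )
  cut(krenning, breaks = c(-0.5, 1.5, 2.5, 4.5), labels = c("0-1", "2", "3-4"))
}
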