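# Shared fixtures: small cohorts built in code at test time.

small_cohort <- function(seed = 1, n_patients = 40, effects = default_effects(),
                         missingness = TRUE) {
  generate_cohort(cohort_config(n_patients = n_patients, effects = effects),
                  seed = seed, missingness = missingness)
}

null_effects <- function() default_effects() |> dplyr::mutate(effect = 0)

# A tiny hand-built cohort with known scores: 3 patients, 5 lesions.
toy_cohort <- function() {
  registry <- tibble::tibble(
    name = c("marker_a", "marker_b", "lesion_size_mm"),
    group = c("Imm", "Lab", "Path"),
    dtype = c("binary", "numeric", "numeric"),
    level = c("patient", "patient", "lesion"),
    missing_rate = 0
  )
  patients <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    eligible = c(TRUE, FALSE, FALSE),
    marker_a = c(1L, 0L, NA),
    marker_b = c(2.5, NA, 0.7)
  )
  lesions <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2", "P3"),
    lesion_id = paste0("L", 1:5),
    site = c("liver", "primary", "liver", "lung", "lymph_node_or_bone"),
    ratio_liver = c(1.5, 1.8, 1.6, 0.5, 1.05),
    ratio_spleen = c(0.9, 1.2, 0.8, 0.3, 0.6),
    lesion_size_mm = c(12, 30, 22, 18, 40)
  )
  lesions$krenning <- krenning_from_ratios(lesions$ratio_liver,
                                           lesions$ratio_spleen)
  lesions$pro_prrt <- lesion_pro_prrt(lesions$krenning)
  prrt_cohort(patients, lesions, registry)
}
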