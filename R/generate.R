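#' Planted covariate effects on lesion uptake
#'
#' The default effect set mirrors the associations reported for the
#' motivating cohort, as additive shifts on the log lesion-to-liver
#' uptake-ratio scale: gastroenteropancreatic origin raises uptake,
#' lung origin and poorly differentiated histology (NEC) lower it, prior
#' oncological treatment lowers it, and CK7 positivity lowers it
#' (equivalently, CK7-negative tumors show higher somatostatin-receptor
#' expression).
#'
#' @return Tibble with columns `feature`, `effect`, `level`.
#' @export
default_effects <- function() {
  tibble(
    feature = c("origin_gep", "origin_lung", "nec", "prior_treatment",
                "ck7_positive"),
    effect = c(0.7, -0.7, -0.8, -0.6, -0.8),
    level = "patient"
  )
}

#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the structure of the motivating single-center cohort:
#' 65 patients (NET:NEC roughly 51:14; origin priors roughly GI 33, lung
#' 10, unknown 7, other 15), about six lesions per patient (392 total in
#' expectation), 100 patient-level and 104 lesion-level features split
#' evenly across the four variable groups, retrospective missingness
#' concentrated in the immunohistochemical and laboratory groups, and a
#' minority PRRT-eligible class.
#'
#' Uptake is log-normal multiplicative: each patient carries a latent
#' log-uptake `mu = beta0 + sum(effect * covariate) + N(0, patient_noise_sd)`
#' and each lesion draws `ratio_liver = exp(mu + N(0, lesion_noise_sd))`,
#' `ratio_spleen = exp(mu - spleen_offset + N(0, lesion_noise_sd))`.
#' `beta0` was fixed once by Monte-Carlo calibration so that default
#' cohorts land near the reference composition (about half the lesions
#' Krenning 3--4 and an eligible-patient fraction near 21/65).
#'
#' @param n_patients Number of patients (default 65).
#' @param lesion_lambda Mean of the shifted-Poisson lesion count
#'   (`1 + Poisson(lesion_lambda)` lesions per patient; default 5.03,
#'   targeting 392 lesions in expectation at 65 patients).
#' @param effects Tibble of planted effects as in [default_effects()];
#'   set `effect` to 0 for a null cohort.
#' @param beta0 Intercept of the latent log lesion-to-liver ratio.
#' @param patient_noise_sd,lesion_noise_sd Between-patient and
#'   within-patient log-scale noise SDs.
#' @param spleen_offset Log-scale shift making spleen-referenced ratios
#'   lower than liver-referenced ones (spleen background uptake is
#'   higher).
#' @param nec_prob,treated_prob,ssa_prob,multi_organ_prob Bernoulli
#'   priors for the corresponding patient covariates.
#' @param origin_probs Named probabilities for tumor origin
#'   (`gep`, `lung`, `unknown`, `other`).
#' @param site_probs Named probabilities for lesion site.
#' @param missing_overrides Optional named numeric vector of per-feature
#'   missing rates overriding the registry defaults.
#' @param seed Default seed used by [generate_cohort()].
#' @return A list with class `prrt_cohort_config`.
#' @export
cohort_config <- function(n_patients = 65,
                          lesion_lambda = 5.03,
                          effects = default_effects(),
                          beta0 = 0.5,
                          patient_noise_sd = 0.6,
                          lesion_noise_sd = 0.35,
                          spleen_offset = 0.35,
                          nec_prob = 14 / 65,
                          treated_prob = 45 / 65,
                          ssa_prob = 13 / 65,
                          multi_organ_prob = 24 / 65,
                          origin_probs = c(gep = 33, lung = 10,
                                           unknown = 7, other = 15) / 65,
                          site_probs = c(liver = 147, lymph_node_or_bone = 160,
                                         lung = 15, other = 23, primary = 47) / 392,
                          missing_overrides = NULL,
                          seed = 1L) {
  check_scalar_number(n_patients, "n_patients", lower = 2)
  check_scalar_number(lesion_lambda, "lesion_lambda", lower = 0)
  check_scalar_number(patient_noise_sd, "patient_noise_sd", lower = 1e-9)
  check_scalar_number(lesion_noise_sd, "lesion_noise_sd", lower = 1e-9)
  check_scalar_number(spleen_offset, "spleen_offset", lower = 0)
  stop_if_not(abs(sum(origin_probs) - 1) < 1e-8, "origin_probs must sum to 1.")
  stop_if_not(abs(sum(site_probs) - 1) < 1e-8, "site_probs must sum to 1.")
  if (is.null(effects)) {
    effects <- default_effects() |> mutate(effect = 0)
  }
  effects <- as_tibble(effects)
  stop_if_not(all(c("feature", "effect") %in% names(effects)) &&
                all(is.finite(effects$effect)),
              "`effects` needs finite `effect` values per `feature`.")
  if (!is.null(missing_overrides)) {
    stop_if_not(is.numeric(missing_overrides) &&
                  !is.null(names(missing_overrides)) &&
                  all(missing_overrides >= 0 & missing_overrides <= 1),
                "`missing_overrides` must be a named vector of rates in [0, 1].")
  }
  structure(
    list(n_patients = as.integer(n_patients), lesion_lambda = lesion_lambda,
         effects = effects, beta0 = beta0,
         patient_noise_sd = patient_noise_sd, lesion_noise_sd = lesion_noise_sd,
         spleen_offset = spleen_offset, nec_prob = nec_prob,
         treated_prob = treated_prob, ssa_prob = ssa_prob,
         multi_organ_prob = multi_organ_prob, origin_probs = origin_probs,
         site_probs = site_probs, missing_overrides = missing_overrides,
         seed = as.integer(seed)),
    class = "prrt_cohort_config"
  )
}

#' Default study-like configuration
#'
#' Convenience alias for `cohort_config()` with all defaults: the
#' configuration whose structure emulates the reference cohort.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A `prrt_cohort_config`.
#' @export
default_cohort_config <- function(...) cohort_config(...)

# Registry of the default feature set: 100 patient-level features
# (25 per variable group) plus 4 lesion-level features.
default_registry <- function(effects = default_effects()) {
  named <- tibble(
    name = c(
      # Onco: origin one-hot, treatment history, spread
      "origin_gep", "origin_lung", "origin_unknown", "origin_other",
      "prior_treatment", "ssa_therapy", "multi_organ",
      # Path
      "nec", "grade", "ki67", "t_stage_high",
      # Imm
      "ck7_positive", "ck20_positive", "ttf1_positive",
      "synaptophysin_positive", "cga_ihc_positive",
      # Lab: serum markers and their elevated-vs-normal flags
      "cga_serum", "nse", "cea", "ca19_9", "afp",
      "cga_elevated", "nse_elevated", "cea_elevated", "ca19_9_elevated",
      "afp_elevated"
    ),
    group = c(rep("Onco", 7), rep("Path", 4), rep("Imm", 5), rep("Lab", 10)),
    dtype = c(rep("binary", 7),
              "binary", "numeric", "numeric", "binary",
              rep("binary", 5),
              rep("numeric", 5), rep("binary", 5)),
    level = "patient",
    missing_rate = c(
      rep(0, 7),
      0, 0, 0.1, 0,
      0.49, 0.65, 0.57, 0.17, 0,
      0.1, 0.3, 0.42, 0.49, 0.68,
      0.1, 0.3, 0.42, 0.49, 0.68
    )
  )
  fill <- function(group, n_bin, n_num, miss) {
    tibble(
      name = c(sprintf("%s_b%02d", tolower(group), seq_len(n_bin)),
               sprintf("%s_x%02d", tolower(group), seq_len(n_num))),
      group = group,
      dtype = c(rep("binary", n_bin), rep("numeric", n_num)),
      level = "patient",
      missing_rate = miss
    )
  }
  noise <- bind_rows(
    fill("Onco", 9, 9, 0.05),
    fill("Path", 11, 10, 0.05),
    fill("Imm", 10, 10, 0.4),
    fill("Lab", 8, 7, 0.3)
  )
  lesion <- tibble(
    name = c("lesion_size_mm", "site_liver", "site_bone_lymph", "site_primary"),
    group = c("Path", "Onco", "Onco", "Onco"),
    dtype = c("numeric", "binary", "binary", "binary"),
    level = "lesion",
    missing_rate = 0
  )
  reg <- bind_rows(named, noise, lesion)
  reg$planted <- reg$name %in% effects$feature[effects$effect != 0]
  reg$effect <- effects$effect[match(reg$name, effects$feature)]
  reg$effect[is.na(reg$effect)] <- 0
  reg
}

#' Generate a synthetic two-level cohort
#'
#' Draws patient covariates (binary via Bernoulli, laboratory markers
#' log-normal), forms each patient's latent log uptake from the planted
#' effects, draws per-lesion liver- and spleen-referenced uptake ratios
#' around it, derives Krenning scores, per-lesion ProPRRT flags and
#' least-active-lesion patient eligibility, then masks feature cells
#' according to the registry's missing rates. Identical seeds give
#' identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param missingness Apply the registry missing rates (default `TRUE`)?
#' @return A [prrt_cohort()] whose `truth` records the planted effects
#'   and seed.
#' @export
generate_cohort <- function(config = default_cohort_config(),
                            seed = config$seed, missingness = TRUE) {
  stop_if_not(inherits(config, "prrt_cohort_config"),
              "`config` must come from cohort_config().")
  registry <- default_registry(config$effects)
  if (!is.null(config$missing_overrides)) {
    ov <- config$missing_overrides
    unknown_ov <- setdiff(names(ov), registry$name)
    stop_if_not(length(unknown_ov) == 0,
                paste("missing_overrides name(s) not in registry:",
                      paste(unknown_ov, collapse = ", ")))
    registry$missing_rate[match(names(ov), registry$name)] <- unname(ov)
  }
  unknown <- setdiff(config$effects$feature, registry$name)
  stop_if_not(length(unknown) == 0,
              paste("Effect feature(s) not in registry:",
                    paste(unknown, collapse = ", ")))

  cohort <- with_seed(derive_seed(seed, 0), {
    n <- config$n_patients
    pid <- sprintf("P%03d", seq_len(n))

    origin <- sample(names(config$origin_probs), n, replace = TRUE,
                     prob = config$origin_probs)
    patients <- tibble(
      patient_id = pid,
      origin_gep = as.integer(origin == "gep"),
      origin_lung = as.integer(origin == "lung"),
      origin_unknown = as.integer(origin == "unknown"),
      origin_other = as.integer(origin == "other"),
      prior_treatment = rbinom(n, 1, config$treated_prob),
      ssa_therapy = rbinom(n, 1, config$ssa_prob),
      multi_organ = rbinom(n, 1, config$multi_organ_prob),
      nec = rbinom(n, 1, config$nec_prob),
      grade = sample(1:3, n, replace = TRUE, prob = c(24, 25, 16) / 65),
      ki67 = rlnorm(n, log(5), 1),
      t_stage_high = rbinom(n, 1, 0.5),
      # CK7 is mostly negative in GI tumors, about 50/50 elsewhere
      ck7_positive = rbinom(n, 1, if_else(origin == "gep", 0.2, 0.5)),
      ck20_positive = rbinom(n, 1, 0.3),
      ttf1_positive = rbinom(n, 1, 0.3),
      synaptophysin_positive = rbinom(n, 1, 0.95),
      cga_ihc_positive = rbinom(n, 1, 0.9),
      cga_serum = rlnorm(n, log(150), 1),
      nse = rlnorm(n, log(15), 0.6),
      cea = rlnorm(n, log(3), 0.8),
      ca19_9 = rlnorm(n, log(20), 1),
      afp = rlnorm(n, log(4), 0.7)
    )
    # elevated-vs-normal flags at conventional upper reference limits
    cuts <- c(cga_serum = 100, nse = 16.3, cea = 5, ca19_9 = 37, afp = 10)
    patients$cga_elevated <- as.integer(patients$cga_serum > cuts["cga_serum"])
    patients$nse_elevated <- as.integer(patients$nse > cuts["nse"])
    patients$cea_elevated <- as.integer(patients$cea > cuts["cea"])
    patients$ca19_9_elevated <- as.integer(patients$ca19_9 > cuts["ca19_9"])
    patients$afp_elevated <- as.integer(patients$afp > cuts["afp"])

    noise <- registry[registry$level == "patient" &
                        grepl("_(b|x)[0-9]+$", registry$name), ]
    for (i in seq_len(nrow(noise))) {
      patients[[noise$name[i]]] <- if (noise$dtype[i] == "binary") {
        rbinom(n, 1, 0.3)
      } else {
        rlnorm(n, 0, 1)
      }
    }

    eff <- config$effects[config$effects$effect != 0, ]
    shift <- rep(0, n)
    for (i in seq_len(nrow(eff))) {
      shift <- shift + eff$effect[i] * patients[[eff$feature[i]]]
    }
    mu <- config$beta0 + shift + rnorm(n, 0, config$patient_noise_sd)

    n_lesions <- 1L + rpois(n, config$lesion_lambda)
    les_pid <- rep(pid, n_lesions)
    les_mu <- rep(mu, n_lesions)
    m <- length(les_pid)
    site <- sample(names(config$site_probs), m, replace = TRUE,
                   prob = config$site_probs)
    ratio_liver <- exp(les_mu + rnorm(m, 0, config$lesion_noise_sd))
    ratio_spleen <- exp(les_mu - config$spleen_offset +
                          rnorm(m, 0, config$lesion_noise_sd))
    kren <- krenning_from_ratios(ratio_liver, ratio_spleen)
    lesions <- tibble(
      patient_id = les_pid,
      lesion_id = sprintf("%s_L%02d", les_pid,
                          unlist(lapply(n_lesions, seq_len))),
      site = site,
      ratio_liver = ratio_liver,
      ratio_spleen = ratio_spleen,
      krenning = kren,
      pro_prrt = lesion_pro_prrt(kren),
      lesion_size_mm = rlnorm(m, log(25), 0.5),
      site_liver = as.integer(site == "liver"),
      site_bone_lymph = as.integer(site == "lymph_node_or_bone"),
      site_primary = as.integer(site == "primary")
    )
    elig <- lesions |>
      group_by(.data$patient_id) |>
      summarise(eligible = all(.data$pro_prrt), .groups = "drop")
    patients <- left_join(tibble(patient_id = pid), elig, by = "patient_id") |>
      bind_cols(patients[setdiff(names(patients), "patient_id")])

    truth <- list(
      seed = as.integer(seed),
      beta0 = config$beta0,
      planted = as.list(setNames(eff$effect, eff$feature))
    )
    prrt_cohort(patients, lesions, registry, truth = truth)
  })

  if (missingness) {
    cohort <- inject_missingness(cohort, seed = derive_seed(seed, 7919))
  }
  cohort
}

#' Mask feature cells completely at random
#'
#' Applies per-feature missing rates to the feature columns of a cohort,
#' emulating the incompleteness of retrospectively collected
#' immunohistochemical and laboratory work-ups. Identifiers, uptake
#' ratios, Krenning scores and outcome flags are never masked.
#'
#' @param cohort A [prrt_cohort()].
#' @param rates Named numeric vector of per-feature rates in \[0,1\];
#'   defaults to the registry's `missing_rate` (plus the config's
#'   `missing_overrides`, already folded into the registry when the
#'   cohort came from [generate_cohort()]).
#' @param seed Integer seed; masking is deterministic given the seed.
#' @return The cohort with masked feature cells.
#' @export
inject_missingness <- function(cohort, rates = NULL, seed = 1L) {
  stop_if_not(inherits(cohort, "prrt_cohort"), "`cohort` must be a prrt_cohort.")
  reg <- cohort$registry
  rate_vec <- setNames(reg$missing_rate, reg$name)
  if (!is.null(rates)) {
    stop_if_not(is.numeric(rates) && !is.null(names(rates)),
                "`rates` must be a named numeric vector.")
    stop_if_not(all(rates >= 0 & rates <= 1), "Missing rates must lie in [0, 1].")
    unknown <- setdiff(names(rates), reg$name)
    stop_if_not(length(unknown) == 0,
                paste("Unknown feature(s):", paste(unknown, collapse = ", ")))
    rate_vec[names(rates)] <- rates
  }
  with_seed(derive_seed(seed, 0), {
    for (lvl in c("patient", "lesion")) {
      tab_name <- if (lvl == "patient") "patients" else "lesions"
      tab <- cohort[[tab_name]]
      for (f in reg$name[reg$level == lvl]) {
        r <- rate_vec[[f]]
        if (r > 0) {
          mask <- runif(nrow(tab)) < r
          tab[[f]][mask] <- NA
        }
      }
      cohort[[tab_name]] <- tab
    }
  })
  cohort
}
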