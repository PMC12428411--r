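#' Pipeline configuration
#'
#' Bundles the stage configurations of the full analysis chain
#' (generate -> benchmark -> importance -> consensus -> validate). Two
#' scale presets exist: `"desk"` (the tested default: 10 splits, 20
#' permutations, tree learners with and without SMOTE over the four
#' single groups plus the full set) and `"full"` (100 splits, 100
#' permutations, all 15 subsets — the study-scale bench, hours of
#' compute).
#'
#' @param generator A [cohort_config()].
#' @param scale `"desk"` or `"full"`.
#' @param learners,smote Bench grid axes (see [bench_grid()]).
#' @param n_splits,n_perm Override the preset's split and permutation
#'   counts (desk preset caps both at 20).
#' @param train_frac,smote_k,eps,fraction,alpha Stage parameters (see
#'   [run_bench()], [run_importance()], [validate_features()]).
#' @param seed Global integer seed.
#' @return A list with class `prrt_pipeline_config`.
#' @export
pipeline_config <- function(generator = default_cohort_config(),
                            scale = c("desk", "full"),
                            learners = c("bagged_trees", "boosted_trees"),
                            smote = c(FALSE, TRUE),
                            n_splits = NULL, n_perm = NULL,
                            train_frac = 0.8, smote_k = 5L, eps = 1e-6,
                            fraction = 0.10, alpha = 0.05, seed = 1L) {
  scale <- match.arg(scale)
  n_splits <- n_splits %||% if (scale == "desk") 10L else 100L
  n_perm <- n_perm %||% if (scale == "desk") 20L else 100L
  if (scale == "desk") {
    stop_if_not(n_splits <= 20 && n_perm <= 20,
                "The desk preset caps n_splits and n_perm at 20.")
  }
  subsets <- if (scale == "desk") {
    c(as.list(variable_groups()), list(variable_groups()))
  } else {
    enumerate_group_subsets()
  }
  structure(
    list(generator = generator, scale = scale, learners = learners,
         smote = smote, subsets = subsets, n_splits = n_splits,
         n_perm = n_perm, train_frac = train_frac, smote_k = smote_k,
         eps = eps, fraction = fraction, alpha = alpha,
         seed = as.integer(seed)),
    class = "prrt_pipeline_config"
  )
}

#' Run the full two-level analysis pipeline
#'
#' Generates (or accepts) a cohort, runs the importance framework at
#' both the lesion and the patient level, intersects the two selections
#' into a consensus list, confirms the consensus features with the
#' nonparametric validation stage, and — when `out_dir` is given —
#' writes every interface file plus a JSON run manifest. Fully
#' deterministic given the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built [prrt_cohort()]; by default one is
#'   generated from `config$generator` with the global seed.
#' @param out_dir Optional output directory for the artifact files
#'   (`consensus.csv`, `fi_ranking_lesion.csv`, `fi_ranking_patient.csv`,
#'   `pi_records_*.csv`, `bench_summary_*.csv`, `validation_results.csv`,
#'   `correlation_triangle_lesion.csv`, `manifest.json`, and the cohort
#'   tables).
#' @return A `prrt_pipeline` list: `cohort`, `lesion` and `patient`
#'   `prrt_fi` objects, `consensus`, `validation`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  stop_if_not(inherits(config, "prrt_pipeline_config"),
              "`config` must come from pipeline_config().")
  t0 <- Sys.time()
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$generator, seed = config$seed)
  }

  fi <- list()
  for (lvl in c("lesion", "patient")) {
    grid <- bench_grid(
      learners = config$learners, smote = config$smote,
      targets = if (lvl == "lesion") "pro_prrt_lesion" else "pro_prrt_patient",
      subsets = config$subsets
    )
    fi[[lvl]] <- run_importance(
      cohort, level = lvl, grid = grid, n_splits = config$n_splits,
      train_frac = config$train_frac, smote_k = config$smote_k,
      n_perm = config$n_perm, eps = config$eps, fraction = config$fraction,
      seed = derive_seed(config$seed, if (lvl == "lesion") 1000 else 2000)
    )
  }

  consensus <- consensus_features(fi$lesion, fi$patient)
  validation <- if (nrow(consensus) > 0) {
    validate_features(cohort, consensus$feature, level = "both",
                      alpha = config$alpha)
  } else {
    tibble()
  }

  manifest <- list(
    seed = config$seed, scale = config$scale,
    n_splits = config$n_splits, n_perm = config$n_perm,
    fraction = config$fraction, eps = config$eps, alpha = config$alpha,
    n_patients = nrow(cohort$patients), n_lesions = nrow(cohort$lesions),
    n_configs_per_level = nrow(fi$lesion$bench),
    n_consensus = nrow(consensus),
    r_version = as.character(getRversion()),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = list(lesion = length(fi$lesion$warnings),
                    patient = length(fi$patient$warnings))
  )

  out <- structure(
    list(cohort = cohort, lesion = fi$lesion, patient = fi$patient,
         consensus = consensus, validation = validation,
         summary = summarize_cohort(cohort), manifest = manifest,
         config = config),
    class = "prrt_pipeline"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    readr::write_csv(consensus, file.path(out_dir, "consensus.csv"), na = "")
    readr::write_csv(validation, file.path(out_dir, "validation_results.csv"),
                     na = "")
    for (lvl in c("lesion", "patient")) {
      readr::write_csv(fi[[lvl]]$ranking,
                       file.path(out_dir, sprintf("fi_ranking_%s.csv", lvl)),
                       na = "")
      readr::write_csv(fi[[lvl]]$pi_records,
                       file.path(out_dir, sprintf("pi_records_%s.csv", lvl)),
                       na = "")
      readr::write_csv(fi[[lvl]]$bench,
                       file.path(out_dir, sprintf("bench_summary_%s.csv", lvl)),
                       na = "")
    }
    if (!is.null(fi$lesion$triangle)) {
      tri <- as_tibble(fi$lesion$triangle, rownames = "feature")
      readr::write_csv(tri, file.path(out_dir, "correlation_triangle_lesion.csv"),
                       na = "")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.prrt_pipeline <- function(x, ...) {
  cat("<prrt_pipeline> seed ", x$manifest$seed, ", scale ", x$manifest$scale,
      "\n", sep = "")
  print(x$cohort)
  cat("  consensus (", nrow(x$consensus), "): ",
      paste(x$consensus$feature, collapse = ", "), "\n", sep = "")
  if (nrow(x$validation) > 0) {
    sig <- x$validation |> filter(.data$significant)
    cat("  validated significant: ", nrow(sig), "/", nrow(x$validation),
        " tests\n", sep = "")
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `prrt_pipeline`.
#' @param ... Unused.
#' @export
tidy.prrt_pipeline <- function(x, ...) {
  x$consensus |>
    left_join(
      x$validation |>
        group_by(.data$feature) |>
        summarise(min_p = min(.data$p_value),
                  n_significant = sum(.data$significant), .groups = "drop"),
      by = "feature"
    )
}

#' @rdname run_pipeline
#' @export
glance.prrt_pipeline <- function(x, ...) {
  tibble(
    n_patients = x$manifest$n_patients,
    n_lesions = x$manifest$n_lesions,
    mean_f1_lesion = mean(x$lesion$bench$mean_f1, na.rm = TRUE),
    mean_f1_patient = mean(x$patient$bench$mean_f1, na.rm = TRUE),
    n_consensus = nrow(x$consensus),
    n_validated = if (nrow(x$validation) > 0) {
      sum(x$validation$significant)
    } else 0L
  )
}
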