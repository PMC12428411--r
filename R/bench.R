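#' Build the benchmark configuration grid
#'
#' One configuration per learner x SMOTE setting x variable-group subset
#' x target. The default grid is the full study bench: tree learners
#' with and without SMOTE over all 15 group combinations.
#'
#' @param learners Learner kinds (see [train_model()]).
#' @param smote Logical vector of SMOTE settings to cross.
#' @param targets Any of `"pro_prrt_lesion"`, `"krenning_bin"`,
#'   `"pro_prrt_patient"`.
#' @param subsets List of variable-group subsets
#'   (default [enumerate_group_subsets()]).
#' @return Tibble with columns `config_id`, `learner`, `smote`, `target`,
#'   `groups` (list-column) and `label`.
#' @export
bench_grid <- function(learners = c("bagged_trees", "boosted_trees"),
                       smote = c(FALSE, TRUE),
                       targets = "pro_prrt_lesion",
                       subsets = enumerate_group_subsets()) {
  stop_if_not(all(learners %in% c("linear", "bagged_trees", "boosted_trees")),
              "Unknown learner kind.")
  stop_if_not(all(targets %in% c("pro_prrt_lesion", "krenning_bin",
                                 "pro_prrt_patient")),
              "Unknown target.")
  grid <- tidyr::expand_grid(
    target = targets, learner = learners, smote = smote,
    groups = subsets
  )
  grid |>
    mutate(
      label = map_chr(.data$groups, subset_label),
      config_id = sprintf("%s|%s|%s|%s", .data$target, .data$learner,
                          if_else(.data$smote, "smote", "raw"), .data$label)
    ) |>
    select("config_id", "learner", "smote", "target", "groups", "label")
}

target_level <- function(target) {
  if (target == "pro_prrt_patient") "patient" else "lesion"
}

target_metric <- function(target) {
  if (target == "krenning_bin") {
    list(average = "macro", positive = NA_character_)
  } else {
    list(average = "binary", positive = "TRUE")
  }
}

# Assemble the modeling frame for one target: outcome factor `y` plus the
# raw (un-imputed) feature columns restricted to `groups`. Lesion-level
# targets join each lesion to its patient's features.
model_frame <- function(cohort, target, groups = variable_groups()) {
  reg <- cohort$registry
  keep <- reg$name[reg$group %in% groups]
  if (target_level(target) == "patient") {
    feats <- intersect(keep, reg$name[reg$level == "patient"])
    y <- factor(cohort$patients$eligible, levels = c("FALSE", "TRUE"))
    x <- cohort$patients[feats]
  } else {
    feats_l <- intersect(keep, reg$name[reg$level == "lesion"])
    feats_p <- intersect(keep, reg$name[reg$level == "patient"])
    joined <- left_join(
      cohort$lesions[c("patient_id", "lesion_id", "krenning", "pro_prrt",
                       feats_l)],
      cohort$patients[c("patient_id", feats_p)],
      by = "patient_id"
    )
    y <- if (target == "krenning_bin") {
      krenning_bin(joined$krenning)
    } else {
      factor(joined$pro_prrt, levels = c("FALSE", "TRUE"))
    }
    x <- joined[c(feats_l, feats_p)]
  }
  stop_if_not(ncol(x) > 0, "No features fall in the requested groups.")
  pid <- if (target_level(target) == "patient") {
    cohort$patients$patient_id
  } else {
    joined$patient_id
  }
  list(y = y, x = x, patient_id = pid)
}

# Shared engine behind run_bench() and run_importance(): fits every
# config x split cell, scores test F1, and (when n_perm > 0) computes
# per-feature permutation importance on the test partition.
bench_engine <- function(cohort, grid, n_splits = 100, train_frac = 0.8,
                         smote_k = 5L, n_perm = 0L, seed = 1L,
                         model_args = list(), split_by = "patient") {
  stop_if_not(split_by %in% c("patient", "row"), "split_by must be 'patient' or 'row'.")
  stop_if_not(inherits(cohort, "prrt_cohort"), "`cohort` must be a prrt_cohort.")
  stop_if_not(is_tibble(grid) && nrow(grid) > 0, "`grid` must be non-empty.")
  check_scalar_number(n_splits, "n_splits", lower = 1)

  results <- vector("list", nrow(grid))
  pi_records <- vector("list", nrow(grid))
  warn_log <- character(0)

  for (i in seq_len(nrow(grid))) {
    cfg <- grid[i, ]
    frame <- model_frame(cohort, cfg$target, cfg$groups[[1]])
    n <- length(frame$y)
    met <- target_metric(cfg$target)
    rows <- vector("list", n_splits)
    pis <- vector("list", n_splits)

    for (s in seq_len(n_splits)) {
      sp <- if (split_by == "patient") {
        grouped_split_indices(frame$patient_id, train_frac, derive_seed(seed, s))
      } else {
        split_indices(n, train_frac, derive_seed(seed, s))
      }
      cell <- withCallingHandlers(
        tryCatch({
          enc <- impute_and_encode(frame$x[sp$train, , drop = FALSE],
                                   frame$x[sp$test, , drop = FALSE],
                                   cohort$registry)
          ytr <- droplevels(frame$y[sp$train])
          xtr <- enc$train
          if (isTRUE(cfg$smote) && nlevels(ytr) >= 2) {
            k_eff <- min(smote_k, min(table(ytr)) - 1L)
            stop_if_not(k_eff >= 1,
                        "SMOTE impossible: a training class has a single member.")
            sm <- smote_oversample(xtr, ytr, k = k_eff,
                                   seed = derive_seed(seed, i * 100000 + s))
            xtr <- sm$x
            ytr <- sm$y
          }
          model <- do.call(train_model, c(
            list(learner = cfg$learner, x = xtr, y = ytr,
                 seed = derive_seed(seed, i * 100000 + s)),
            model_args))
          pred <- predict(model, enc$test)
          yte <- frame$y[sp$test]
          f1 <- f1_score(yte, pred, met$average, met$positive)
          pi <- NULL
          if (n_perm > 0) {
            pi <- pi_all_features(model, enc$test, yte, enc$feature_of,
                                  n_perm = n_perm,
                                  seed = derive_seed(seed, i * 100000 + s + 50000),
                                  average = met$average, positive = met$positive)
          }
          list(f1 = f1, error = NA_character_, pi = pi)
        }, error = function(e) {
          list(f1 = NA_real_, error = conditionMessage(e), pi = NULL)
        }),
        warning = function(w) {
          warn_log <<- c(warn_log, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      rows[[s]] <- tibble(
        config_id = cfg$config_id, learner = cfg$learner, smote = cfg$smote,
        target = cfg$target, label = cfg$label, split = s,
        f1 = cell$f1, n_train = length(sp$train), n_test = length(sp$test),
        error = cell$error
      )
      if (!is.null(cell$pi)) {
        pis[[s]] <- tibble(config_id = cfg$config_id, split = s,
                           feature = names(cell$pi), pi = unname(cell$pi),
                           n_perm = n_perm)
      }
    }
    results[[i]] <- list_rbind(rows)
    pi_records[[i]] <- list_rbind(pis[!vapply(pis, is.null, TRUE)])
  }

  results <- list_rbind(results)
  summary <- results |>
    group_by(.data$config_id, .data$learner, .data$smote, .data$target,
             .data$label) |>
    summarise(mean_f1 = mean(.data$f1, na.rm = TRUE),
              sd_f1 = sd(.data$f1, na.rm = TRUE),
              n_ok = sum(!is.na(.data$f1)),
              n_failed = sum(is.na(.data$f1)),
              .groups = "drop")
  list(results = results, summary = summary,
       pi_records = list_rbind(pi_records[!vapply(pi_records, is.null, TRUE)]),
       warnings = warn_log)
}

#' Run the model benchmark grid
#'
#' Fits every configuration of `grid` on `n_splits` random train/test
#' partitions, scoring the F1 of each fit on its untouched test rows.
#' Imputation statistics and SMOTE see training rows only. Failed cells
#' (e.g. a single-class training draw) are recorded and excluded from
#' the per-configuration means.
#'
#' @param cohort A [prrt_cohort()].
#' @param grid A [bench_grid()].
#' @param n_splits Number of random splits per configuration
#'   (default 100).
#' @param train_frac Training fraction (default 0.8).
#' @param smote_k SMOTE neighbor count (default 5; reduced per split
#'   when a minority class is smaller).
#' @param seed Integer seed; split `s` uses the derived seed `seed + s`,
#'   so the same partitions pair configurations.
#' @param model_args Named list of hyperparameter overrides passed on to
#'   [train_model()] (e.g. `list(nrounds = 60)`).
#' @param split_by `"patient"` (default) keeps each patient's lesions on
#'   one side of every partition ([grouped_split_indices()]); `"row"`
#'   splits lesion rows independently ([split_indices()]).
#' @return A `prrt_bench`: `results` (one row per configuration x
#'   split), `summary` (per-configuration mean/SD F1 and failure
#'   counts), `grid`, and collected `warnings`.
#' @export
run_bench <- function(cohort, grid = bench_grid(), n_splits = 100,
                      train_frac = 0.8, smote_k = 5L, seed = 1L,
                      model_args = list(), split_by = c("patient", "row")) {
  split_by <- match.arg(split_by)
  eng <- bench_engine(cohort, grid, n_splits = n_splits,
                      train_frac = train_frac, smote_k = smote_k,
                      n_perm = 0L, seed = seed, model_args = model_args,
                      split_by = split_by)
  structure(
    list(results = eng$results, summary = eng$summary, grid = grid,
         warnings = eng$warnings,
         params = list(n_splits = n_splits, train_frac = train_frac,
                       smote_k = smote_k, seed = seed, split_by = split_by)),
    class = "prrt_bench"
  )
}

#' @export
print.prrt_bench <- function(x, ...) {
  cat("<prrt_bench> ", nrow(x$summary), " configs x ", x$params$n_splits,
      " splits\n", sep = "")
  best <- x$summary |> arrange(desc(.data$mean_f1)) |> slice(1)
  cat(sprintf("  mean F1 %.3f; best %.3f (%s)\n",
              mean(x$summary$mean_f1, na.rm = TRUE), best$mean_f1,
              best$config_id))
  invisible(x)
}

#' @rdname run_bench
#' @param x A `prrt_bench`.
#' @param ... Unused.
#' @export
tidy.prrt_bench <- function(x, ...) x$summary

#' @rdname run_bench
#' @export
glance.prrt_bench <- function(x, ...) {
  best <- x$summary |> arrange(desc(.data$mean_f1)) |> slice(1)
  tibble(
    n_configs = nrow(x$summary),
    n_splits = x$params$n_splits,
    mean_f1 = mean(x$summary$mean_f1, na.rm = TRUE),
    best_f1 = best$mean_f1,
    best_config = best$config_id,
    n_failed_cells = sum(x$summary$n_failed)
  )
}

#' Heat-map of mean F1 over the benchmark grid
#'
#' @param object A `prrt_bench`.
#' @param ... Unused.
#' @return A ggplot: group subsets against learner/SMOTE combinations,
#'   tile fill = mean F1, faceted by target.
#' @export
autoplot.prrt_bench <- function(object, ...) {
  dat <- object$summary |>
    mutate(model = paste0(.data$learner, if_else(.data$smote, "+SMOTE", "")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$model,
                                    fill = .data$mean_f1)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean_f1)),
                       size = 2.6) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "mean F1") +
    ggplot2::facet_wrap(~target, ncol = 1) +
    ggplot2::labs(x = "variable-group subset", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
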