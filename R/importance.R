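# Permutation-importance consensus framework: stabilized permutation
# importance per model, F1-normalized model weights, cross-model
# aggregation, top-fraction selection, and lesion/patient consensus.

# Permutation importance for every raw feature of one fitted cell.
# Encoded columns deriving from the same raw feature (value + missing
# indicator) are permuted jointly with one row permutation. For speed,
# the n_perm permuted copies of the test matrix are stacked — several
# features at a time — into one matrix per predict call, so the
# per-call overhead is amortized over features.
feat_cols <- function(x_test, feature_of, f) {
  which(colnames(x_test) %in% names(feature_of)[feature_of == f])
}

pi_all_features <- function(model, x_test, y_test, feature_of, n_perm = 100L,
                            seed = 1L, average = "binary", positive = "TRUE") {
  n <- nrow(x_test)
  base_f1 <- f1_score(y_test, predict(model, x_test), average, positive)
  feats <- unique(feature_of)
  rows_per_feat <- n * n_perm
  big_idx <- rep(seq_len(n), n_perm)
  big0 <- x_test[big_idx, , drop = FALSE]
  out <- setNames(numeric(length(feats)), feats)

  feats_per_call <- max(1L, as.integer(1e6 %/% rows_per_feat))
  chunks <- split(seq_along(feats), (seq_along(feats) - 1L) %/% feats_per_call)
  for (ch in chunks) {
    live <- integer(0)
    for (j in ch) {
      cols <- feat_cols(x_test, feature_of, feats[j])
      keep <- any(apply(x_test[, cols, drop = FALSE], 2,
                        function(v) length(unique(v)) > 1L))
      if (keep) live <- c(live, j) # constant feature: permutation is a no-op
    }
    if (length(live) == 0) next
    stack <- big0[rep.int(seq_len(rows_per_feat), length(live)), , drop = FALSE]
    for (k in seq_along(live)) {
      j <- live[k]
      cols <- feat_cols(x_test, feature_of, feats[j])
      perm_idx <- with_seed(derive_seed(seed, j), {
        unlist(lapply(seq_len(n_perm), function(p) sample.int(n)))
      })
      rows <- (k - 1L) * rows_per_feat + seq_len(rows_per_feat)
      stack[rows, cols] <- x_test[perm_idx, cols]
    }
    pred <- predict(model, stack)
    for (k in seq_along(live)) {
      offset <- (k - 1L) * rows_per_feat
      f1s <- vapply(seq_len(n_perm), function(p) {
        sel <- offset + (p - 1L) * n + seq_len(n)
        f1_score(y_test, pred[sel], average, positive)
      }, 0)
      out[feats[live[k]]] <- base_f1 - mean(f1s)
    }
  }
  out
}

#' Permutation importance of one feature
#'
#' Mean decrease in F1 when the feature's column is randomly permuted
#' `n_perm` times while all other columns stay unchanged: `F1(original)
#' - mean F1(permuted)`. May be negative when permuting accidentally
#' helps. Permutation happens within the supplied (test) partition, so
#' no training information is involved.
#'
#' @param model A fitted [train_model()] object.
#' @param x_test Numeric feature matrix (the encoded test partition).
#' @param y_test True classes for `x_test`.
#' @param feature Column name to permute.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @param average,positive F1 averaging, as in [f1_score()].
#' @return A single numeric; 0 (with a warning) for a constant column.
#' @export
permutation_importance <- function(model, x_test, y_test, feature,
                                   n_perm = 100L, seed = 1L,
                                   average = c("binary", "macro"),
                                   positive = "TRUE") {
  average <- match.arg(average)
  stop_if_not(feature %in% colnames(x_test),
              sprintf("Feature '%s' is not a column of `x_test`.", feature))
  if (length(unique(x_test[, feature])) == 1L) {
    rlang::warn(sprintf("Feature '%s' is constant; importance is 0.", feature))
    return(0)
  }
  feature_of <- setNames(colnames(x_test), colnames(x_test))
  pi_all_features(model, x_test, y_test,
                  feature_of[feature_of == feature], n_perm = n_perm,
                  seed = seed, average = average, positive = positive)[[feature]]
}

#' Stabilize permutation importance across splits
#'
#' Raw permutation importance fluctuates between repeated train/test
#' splits; the stabilized value is the mean of its absolute magnitude
#' over a configuration's splits.
#'
#' @param pi_records Tibble with columns `config_id`, `split`, `feature`,
#'   `pi` (as produced by [run_importance()]).
#' @return Tibble `config_id`, `feature`, `stab_pi` (non-negative),
#'   `n_splits_used`.
#' @export
stabilize_pi <- function(pi_records) {
  stop_if_not(all(c("config_id", "feature", "pi") %in% names(pi_records)),
              "`pi_records` needs columns config_id, feature, pi.")
  pi_records |>
    group_by(.data$config_id, .data$feature) |>
    summarise(stab_pi = mean(abs(.data$pi), na.rm = TRUE),
              n_splits_used = sum(!is.na(.data$pi)), .groups = "drop")
}

#' F1-normalized model weights
#'
#' Each configuration's mean F1 is divided by the mean F1 over all
#' configurations, so the weights average to exactly 1: strong models
#' carry proportionally more weight in the aggregated importance,
#' weak models less.
#'
#' @param mean_f1 Named numeric vector (names = config ids) or a tibble
#'   with columns `config_id` and `mean_f1`.
#' @return Tibble `config_id`, `mean_f1`, `weight`.
#' @export
model_weights <- function(mean_f1) {
  if (is.data.frame(mean_f1)) {
    stop_if_not(all(c("config_id", "mean_f1") %in% names(mean_f1)),
                "Need columns config_id and mean_f1.")
    tab <- as_tibble(mean_f1[c("config_id", "mean_f1")])
  } else {
    stop_if_not(is.numeric(mean_f1) && !is.null(names(mean_f1)),
                "`mean_f1` must be a named numeric vector or a tibble.")
    tab <- tibble(config_id = names(mean_f1), mean_f1 = unname(mean_f1))
  }
  stop_if_not(all(tab$mean_f1 >= 0 & tab$mean_f1 <= 1, na.rm = TRUE),
              "Mean F1 values must lie in [0, 1].")
  overall <- mean(tab$mean_f1, na.rm = TRUE)
  stop_if_not(is.finite(overall) && overall > 0,
              "All-zero mean F1: weights undefined.")
  tab |> mutate(weight = .data$mean_f1 / overall)
}

#' Correlation-based relevance filter
#'
#' Drops features whose stabilized permutation importance stays below
#' `eps` in every configuration — features whose importance pattern
#' shows no correlation with model performance — and reports the
#' feature-feature Spearman correlation triangle of the retained
#' features as an inspection artifact.
#'
#' @param pi_records PI records as in [stabilize_pi()].
#' @param feature_data Data frame of raw feature columns (used for the
#'   correlation triangle; pairwise-complete Spearman).
#' @param eps Drop threshold on mean |PI| (default `1e-6`); `eps = 0`
#'   disables the filter.
#' @return List: `retained` (character), `dropped` (character),
#'   `triangle` (lower-triangular correlation matrix, upper `NA`).
#' @export
correlation_filter <- function(pi_records, feature_data = NULL, eps = 1e-6) {
  check_scalar_number(eps, "eps", lower = 0)
  stab <- stabilize_pi(pi_records)
  keep_tab <- stab |>
    group_by(.data$feature) |>
    summarise(max_pi = max(.data$stab_pi), .groups = "drop")
  retained <- sort(keep_tab$feature[keep_tab$max_pi >= eps | eps == 0])
  dropped <- sort(setdiff(keep_tab$feature, retained))
  stop_if_not(length(retained) > 0,
              "All features dropped; decrease `eps`.")
  triangle <- NULL
  if (!is.null(feature_data)) {
    cols <- intersect(retained, names(feature_data))
    if (length(cols) >= 2) {
      m <- suppressWarnings(
        cor(as.matrix(as.data.frame(lapply(feature_data[cols], as.numeric))),
            method = "spearman", use = "pairwise.complete.obs")
      )
      m[upper.tri(m)] <- NA
      triangle <- m
    }
  }
  list(retained = retained, dropped = dropped, triangle = triangle)
}

#' Aggregate stabilized importance across models
#'
#' The final feature importance is the weighted mean of the stabilized
#' |PI| over all configurations that contain the feature, with the
#' F1-normalized model weights: `fi_f = sum(w_m * stabPI_mf) /
#' sum(w_m)` over covering configurations `m`. Reported values are
#' max-normalized to 1; ranking is by `fi` descending with lexicographic
#' tie-breaks.
#'
#' @param stabilized Output of [stabilize_pi()].
#' @param weights Output of [model_weights()].
#' @param retained Optional character vector restricting the ranking
#'   (e.g. from [correlation_filter()]).
#' @return Tibble `feature`, `fi`, `fi_norm`, `rank`, `n_configs`.
#' @export
aggregate_fi <- function(stabilized, weights, retained = NULL) {
  stop_if_not(all(stabilized$config_id %in% weights$config_id),
              "Every PI configuration needs a weight.")
  tab <- stabilized |>
    left_join(weights[c("config_id", "weight")], by = "config_id")
  if (!is.null(retained)) tab <- filter(tab, .data$feature %in% retained)
  stop_if_not(nrow(tab) > 0, "Empty importance table.")
  out <- tab |>
    group_by(.data$feature) |>
    summarise(fi = sum(.data$weight * .data$stab_pi) / sum(.data$weight),
              n_configs = n(), .groups = "drop") |>
    arrange(desc(.data$fi), .data$feature) |>
    mutate(fi_norm = if (max(.data$fi) > 0) .data$fi / max(.data$fi) else .data$fi,
           rank = row_number())
  out[c("feature", "fi", "fi_norm", "rank", "n_configs")]
}

#' Select the top fraction of a ranking
#'
#' Retains the `ceiling(fraction * nrow(ranking))` highest-ranked
#' features (the study's "top 10%" rule).
#'
#' @param ranking Output of [aggregate_fi()].
#' @param fraction Fraction in (0, 1\] (default 0.10).
#' @return Character vector of selected feature names, best first.
#' @export
select_top <- function(ranking, fraction = 0.10) {
  check_scalar_number(fraction, "fraction", lower = 1e-12, upper = 1)
  stop_if_not(is.data.frame(ranking) && nrow(ranking) > 0,
              "`ranking` must be a non-empty ranking table.")
  n_sel <- ceiling(fraction * nrow(ranking))
  ranking |> arrange(.data$rank) |> slice(seq_len(n_sel)) |> pull("feature")
}

#' Lesion/patient consensus features
#'
#' Features selected at both analysis levels, ordered by the mean of
#' their two max-normalized importance values.
#'
#' @param lesion,patient `prrt_fi` objects (or their ranking tibbles,
#'   each with a `selected` column) for the two levels.
#' @return Tibble `feature`, `fi_lesion`, `fi_patient`, `fi_mean`;
#'   empty (with a warning) when the selected sets are disjoint.
#' @export
consensus_features <- function(lesion, patient) {
  rk <- function(x) if (inherits(x, "prrt_fi")) x$ranking else as_tibble(x)
  rl <- rk(lesion)
  rp <- rk(patient)
  stop_if_not(all(c("feature", "fi_norm", "selected") %in% names(rl)) &&
                all(c("feature", "fi_norm", "selected") %in% names(rp)),
              "Rankings need feature, fi_norm and selected columns.")
  shared <- intersect(rl$feature[rl$selected], rp$feature[rp$selected])
  if (length(shared) == 0) {
    rlang::warn("No feature is selected at both levels; consensus is empty.")
  }
  tibble(feature = shared) |>
    left_join(rl |> select("feature", fi_lesion = "fi_norm"), by = "feature") |>
    left_join(rp |> select("feature", fi_patient = "fi_norm"), by = "feature") |>
    mutate(fi_mean = (.data$fi_lesion + .data$fi_patient) / 2) |>
    arrange(desc(.data$fi_mean), .data$feature)
}

#' Run the permutation-importance framework at one level
#'
#' Executes the full importance chain for a cohort at the lesion or the
#' patient level: benchmark every configuration over repeated splits,
#' compute per-feature permutation importance on each test partition,
#' stabilize across splits, filter negligible features, weight models by
#' normalized F1, aggregate to a final feature-importance ranking, and
#' mark the selected top fraction.
#'
#' @param cohort A [prrt_cohort()].
#' @param level `"lesion"` or `"patient"`.
#' @param grid Optional [bench_grid()]; defaults to tree learners with
#'   and without SMOTE over all 15 group subsets, targeting
#'   `pro_prrt_lesion` or `pro_prrt_patient` as per `level`.
#' @param n_splits,train_frac,smote_k As in [run_bench()].
#' @param n_perm Permutations per feature (default 100).
#' @param eps Relevance-filter threshold (default `1e-6`).
#' @param fraction Selection fraction (default 0.10).
#' @param seed Integer seed.
#' @param model_args Named list of hyperparameter overrides passed on to
#'   [train_model()].
#' @param split_by Partitioning mode, as in [run_bench()].
#' @return A `prrt_fi`: `ranking` (with `selected`), `pi_records`,
#'   `bench` summary, `weights`, `retained`/`dropped`, `triangle`, and
#'   the parameters used.
#' @export
run_importance <- function(cohort, level = c("lesion", "patient"),
                           grid = NULL, n_splits = 100, train_frac = 0.8,
                           smote_k = 5L, n_perm = 100L, eps = 1e-6,
                           fraction = 0.10, seed = 1L, model_args = list(),
                           split_by = c("patient", "row")) {
  split_by <- match.arg(split_by)
  level <- match.arg(level)
  if (is.null(grid)) {
    grid <- bench_grid(
      targets = if (level == "lesion") "pro_prrt_lesion" else "pro_prrt_patient"
    )
  }
  stop_if_not(all(map_chr(grid$target, target_level) == level),
              "Every grid target must match `level`.")
  eng <- bench_engine(cohort, grid, n_splits = n_splits,
                      train_frac = train_frac, smote_k = smote_k,
                      n_perm = n_perm, seed = seed, model_args = model_args,
                      split_by = split_by)
  stop_if_not(nrow(eng$pi_records) > 0, "No permutation importance computed.")

  stab <- stabilize_pi(eng$pi_records)
  feature_data <- model_frame(cohort, grid$target[1], variable_groups())$x
  filt <- correlation_filter(eng$pi_records, feature_data, eps = eps)
  wts <- model_weights(eng$summary)
  ranking <- aggregate_fi(stab, wts, retained = filt$retained)
  sel <- select_top(ranking, fraction)
  ranking$selected <- ranking$feature %in% sel

  structure(
    list(level = level, ranking = ranking, pi_records = eng$pi_records,
         bench = eng$summary, weights = wts, retained = filt$retained,
         dropped = filt$dropped, triangle = filt$triangle,
         warnings = eng$warnings,
         params = list(n_splits = n_splits, train_frac = train_frac,
                       smote_k = smote_k, n_perm = n_perm, eps = eps,
                       fraction = fraction, seed = seed, split_by = split_by)),
    class = "prrt_fi"
  )
}

#' @export
print.prrt_fi <- function(x, ...) {
  cat("<prrt_fi> ", x$level, "-level ranking of ", nrow(x$ranking),
      " features (", sum(x$ranking$selected), " selected)\n", sep = "")
  top <- x$ranking |> arrange(.data$rank) |> slice(1:min(5, nrow(x$ranking)))
  cat("  top:", paste(top$feature, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname run_importance
#' @param x A `prrt_fi`.
#' @param ... Unused.
#' @export
tidy.prrt_fi <- function(x, ...) x$ranking

#' @rdname run_importance
#' @export
glance.prrt_fi <- function(x, ...) {
  tibble(
    level = x$level,
    n_features = nrow(x$ranking),
    n_selected = sum(x$ranking$selected),
    n_dropped = length(x$dropped),
    n_configs = nrow(x$bench),
    mean_f1 = mean(x$bench$mean_f1, na.rm = TRUE)
  )
}

#' Bar chart of the aggregated feature-importance ranking
#'
#' @param object A `prrt_fi`.
#' @param top_n Number of features to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prrt_fi <- function(object, top_n = 20, ...) {
  dat <- object$ranking |>
    arrange(.data$rank) |>
    slice(seq_len(min(top_n, nrow(object$ranking)))) |>
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fi_norm, y = .data$feature,
                                    fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#21908C", `FALSE` = "grey70"),
                               name = "selected") +
    ggplot2::labs(x = "feature importance (max-normalized)", y = NULL,
                  title = paste0(object$level, "-level importance ranking")) +
    ggplot2::theme_minimal()
}
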