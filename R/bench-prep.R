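#' Random train/test partition
#'
#' Draws one simple random 80/20-style split. Repeated splitting with
#' derived seeds (`seed + split`) is how the benchmark obtains robust
#' performance estimates.
#'
#' @param n_rows Number of rows (>= 5).
#' @param train_frac Training fraction in (0, 1); `round(train_frac *
#'   n_rows)` rows go to training.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_indices <- function(n_rows, train_frac = 0.8, seed = 1L) {
  check_scalar_number(n_rows, "n_rows", lower = 5)
  check_scalar_number(train_frac, "train_frac", lower = 1e-9, upper = 1 - 1e-9)
  n_train <- round(train_frac * n_rows)
  stop_if_not(n_train >= 2 && n_rows - n_train >= 2,
              "Split leaves fewer than 2 train or test rows.")
  train <- with_seed(seed, sort(sample.int(n_rows, n_train)))
  list(train = train, test = setdiff(seq_len(n_rows), train))
}

#' Patient-grouped train/test partition
#'
#' Splits at the patient level and lets every lesion follow its patient,
#' so no patient's lesions straddle the partition. This is the default
#' for lesion-level targets: with several near-identical lesion rows per
#' patient, row-wise splitting lets models recognize patients across the
#' partition and overstates performance.
#'
#' @param group_ids Vector of one group label (patient id) per row.
#' @param train_frac Fraction of groups assigned to training.
#' @param seed Integer seed.
#' @return List with integer row vectors `train` and `test`.
#' @export
grouped_split_indices <- function(group_ids, train_frac = 0.8, seed = 1L) {
  check_scalar_number(train_frac, "train_frac", lower = 1e-9, upper = 1 - 1e-9)
  groups <- unique(group_ids)
  n_g <- length(groups)
  stop_if_not(n_g >= 5, "Need at least 5 groups to split.")
  n_train <- round(train_frac * n_g)
  stop_if_not(n_train >= 2 && n_g - n_train >= 2,
              "Split leaves fewer than 2 train or test groups.")
  train_g <- with_seed(seed, sample(groups, n_train))
  rows <- seq_along(group_ids)
  list(train = rows[group_ids %in% train_g],
       test = rows[!group_ids %in% train_g])
}

#' SMOTE minority oversampling
#'
#' Balances class counts by interpolated synthetic minority samples:
#' each synthetic point is `x + lambda * (x_nn - x)` with `lambda`
#' uniform in \[0, 1) and `x_nn` one of the `k` nearest same-class
#' neighbors of `x` (Euclidean). Original rows are retained unchanged;
#' every class is topped up to the majority count. Applied to training
#' data only by the benchmark, so test-set performance is never
#' inflated.
#'
#' @param x Numeric matrix of encoded training features.
#' @param y Class vector (factor or coercible) aligned with `x` rows.
#' @param k Number of nearest neighbors (default 5); reduced with a
#'   warning when a minority class has fewer than `k + 1` members.
#' @param seed Integer seed.
#' @return List with matrix `x` and factor `y`, original rows first.
#' @export
smote_oversample <- function(x, y, k = 5L, seed = 1L) {
  stop_if_not(is.matrix(x) && is.numeric(x), "`x` must be a numeric matrix.")
  y <- factor(y)
  stop_if_not(nrow(x) == length(y), "`x` and `y` lengths differ.")
  counts <- table(y)
  n_major <- max(counts)
  new_x <- list()
  new_y <- list()
  with_seed(seed, {
    for (cls in names(counts)[counts < n_major]) {
      idx <- which(y == cls)
      n_min <- length(idx)
      stop_if_not(n_min >= 2,
                  sprintf("Class '%s' has a single member; reduce k or skip SMOTE.",
                          cls))
      k_use <- k
      if (k_use >= n_min) {
        k_use <- n_min - 1L
        rlang::warn(sprintf(
          "SMOTE k reduced from %d to %d for class '%s' (minority size %d).",
          k, k_use, cls, n_min))
      }
      xm <- x[idx, , drop = FALSE]
      d <- as.matrix(stats::dist(xm))
      diag(d) <- Inf
      # row i -> indices of its k_use nearest same-class neighbors
      nn <- apply(d, 1, function(r) order(r)[seq_len(k_use)], simplify = FALSE)
      n_new <- n_major - n_min
      base <- sample.int(n_min, n_new, replace = TRUE)
      pick <- vapply(base, function(b) nn[[b]][sample.int(k_use, 1L)], 1L)
      lam <- runif(n_new)
      synth <- xm[base, , drop = FALSE] +
        lam * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
      new_x[[cls]] <- synth
      new_y[[cls]] <- rep(cls, n_new)
    }
  })
  x_out <- do.call(rbind, c(list(x), unname(new_x)))
  y_out <- factor(c(as.character(y), unlist(unname(new_y))), levels = levels(y))
  rownames(x_out) <- NULL
  list(x = x_out, y = y_out)
}

#' Impute and encode features, fitting on training rows only
#'
#' Numeric features are filled with the training-column median; binary
#' features with the training mode plus a `<name>_missing` indicator
#' column (added when the training column has missing cells). All
#' statistics are fit on training rows and applied unchanged to test
#' rows, so no test information leaks into the model. Columns that are
#' entirely missing in training are dropped with a warning.
#'
#' @param train,test Data frames of raw feature columns (same columns).
#' @param registry Feature registry giving each column's dtype; columns
#'   absent from the registry are treated as numeric.
#' @return List with numeric matrices `train` and `test` and the vector
#'   `feature_of`: for every encoded column, the raw feature it derives
#'   from (used to permute a feature's columns jointly).
#' @export
impute_and_encode <- function(train, test, registry = NULL) {
  stop_if_not(identical(names(train), names(test)),
              "`train` and `test` must share columns.")
  dtype <- setNames(rep("numeric", ncol(train)), names(train))
  if (!is.null(registry)) {
    hit <- intersect(names(train), registry$name)
    dtype[hit] <- registry$dtype[match(hit, registry$name)]
  }
  cols_tr <- list()
  cols_te <- list()
  feature_of <- character(0)
  dropped <- character(0)
  for (nm in names(train)) {
    a <- as.numeric(train[[nm]])
    b <- as.numeric(test[[nm]])
    if (all(is.na(a))) {
      dropped <- c(dropped, nm)
      next
    }
    if (dtype[[nm]] == "binary") {
      obs <- a[!is.na(a)]
      fill <- as.numeric(names(which.max(table(obs))))
      if (anyNA(a)) {
        cols_tr[[paste0(nm, "_missing")]] <- as.numeric(is.na(a))
        cols_te[[paste0(nm, "_missing")]] <- as.numeric(is.na(b))
        feature_of <- c(feature_of, setNames(nm, paste0(nm, "_missing")))
      }
    } else {
      fill <- median(a, na.rm = TRUE)
    }
    a[is.na(a)] <- fill
    b[is.na(b)] <- fill
    cols_tr[[nm]] <- a
    cols_te[[nm]] <- b
    feature_of <- c(feature_of, setNames(nm, nm))
  }
  if (length(dropped) > 0) {
    rlang::warn(paste("Dropped all-missing training column(s):",
                      paste(dropped, collapse = ", ")))
  }
  stop_if_not(length(cols_tr) > 0, "All feature columns were dropped.")
  list(
    train = do.call(cbind, cols_tr),
    test = do.call(cbind, cols_te),
    feature_of = feature_of
  )
}

#' F1 score
#'
#' Harmonic mean of positive predictive value and sensitivity. Binary
#' averaging scores the designated positive class (the PRRT-suitable
#' label); macro averaging takes the unweighted mean of per-class F1
#' (used for the three-bin Krenning target). A class with no predicted
#' and no true positives contributes 0, so the score is always defined.
#'
#' @param y_true,y_pred Class vectors of equal length.
#' @param average `"binary"` or `"macro"`.
#' @param positive Positive class label for binary averaging (default
#'   `"TRUE"`).
#' @return F1 in \[0, 1\].
#' @examples
#' f1_score(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE, TRUE)) # 2/3
#' @export
f1_score <- function(y_true, y_pred, average = c("binary", "macro"),
                     positive = "TRUE") {
  average <- match.arg(average)
  stop_if_not(length(y_true) == length(y_pred),
              "`y_true` and `y_pred` lengths differ.")
  yt <- as.character(y_true)
  yp <- as.character(y_pred)
  one_f1 <- function(cls) {
    tp <- sum(yt == cls & yp == cls)
    fp <- sum(yt != cls & yp == cls)
    fn <- sum(yt == cls & yp != cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  if (average == "binary") {
    stop_if_not(length(unique(yt)) <= 2,
                "Binary averaging needs a 2-class target.")
    one_f1(positive)
  } else {
    mean(vapply(sort(unique(yt)), one_f1, 0))
  }
}
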