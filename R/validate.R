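#' Donor-wise k-fold assignment
#'
#' Shuffles donors with the given seed and deals them round-robin into `k`
#' folds, stratified (when `strata` is given) so each fold draws donors
#' from every fluid where possible. All of a donor's spectra always share
#' one fold, so no donor leaks between training and test sets.
#'
#' @param donor_ids Donor id per spectrum (duplicates allowed) or the
#'   unique donor ids.
#' @param k Number of folds.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @param strata Optional stratum (e.g. fluid) per entry of `donor_ids`;
#'   donors are dealt within strata.
#' @return Object of class `cv_split`: data frame `donor_id`, `fold`
#'   (0-based) with attributes `k` and `seed`.
#' @export
donor_kfold <- function(donor_ids, k = 5L, seed = 1L, strata = NULL) {
  df <- unique(data.frame(donor_id = as.character(donor_ids),
                          stratum = if (is.null(strata)) "all"
                          else as.character(strata)))
  if (anyDuplicated(df$donor_id)) {
    stop("metadata error: a donor appears in multiple strata", call. = FALSE)
  }
  if (nrow(df) < k) {
    stop("size error: fewer donors than folds", call. = FALSE)
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(split(df$donor_id, df$stratum), function(d) {
    d <- sample(d)
    data.frame(donor_id = d, fold = (seq_along(d) - 1L) %% k)
  }))
  rownames(out) <- NULL
  structure(out[order(out$donor_id), ], k = k, seed = seed,
            class = c("cv_split", "data.frame"))
}

#' Confusion matrix of assignments
#'
#' Rows are actual fluids (interferents collapsed to `non_bf`); columns are
#' the predicted fluids plus `OUTLIER`.
#'
#' @param actual Actual fluid labels.
#' @param predicted Predicted labels (fluid or `"OUTLIER"`).
#' @param class_order Fluid vocabulary for the axes.
#' @return Integer matrix; row sums equal the per-fluid sample counts.
#' @export
confusion_matrix <- function(actual, predicted,
                             class_order = fluid_labels()) {
  actual <- ifelse(startsWith(actual, "non_bf:"), "non_bf", actual)
  rows <- c(class_order, if (any(actual == "non_bf")) "non_bf")
  cols <- c(class_order, "OUTLIER")
  tab <- table(factor(actual, rows), factor(predicted, cols))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c("actual", "predicted")
  m
}

.age_stratum_names <- function(age_days) {
  map <- c("1" = "1 day", "7" = "1 week", "30" = "1 month",
           "90" = "3 months", "150" = "5 months", "240" = "8 months")
  nm <- map[as.character(age_days)]
  ifelse(is.na(nm), paste0(age_days, " days"), nm)
}

#' Donor-wise cross-validation of a discrimination scheme
#'
#' For every fold, trains the chosen scheme on the training donors'
#' spectra of the training ages (1 day by default; set
#' `train_ages = "all"` to learn aged variance as well) and predicts every
#' spectrum of the held-out donors, of all ages. Interferent spectra
#' (`non_bf:*` labels) are dealt into folds as test-only donors and are
#' never trained on. Counts are accumulated into one confusion matrix per
#' age stratum.
#'
#' @param data Preprocessed [spectra_set()].
#' @param scheme `"flat"` or `"tree"`.
#' @param alpha Q-test significance (defaults: 0.005 flat, 0.00005 tree).
#' @param k_folds Number of donor-wise folds.
#' @param K_max Largest candidate component count per model.
#' @param seed Seed controlling the fold split and nested selection folds.
#' @param train_ages Ages (days) used for training, or `"all"`.
#' @param use_q Apply the Q-tests; with `FALSE` the raw PLS-LDA assignment
#'   is evaluated (no outlier category among body fluids).
#' @return Named list of confusion matrices, one per age stratum present,
#'   with the per-spectrum predictions in attribute `assignments`.
#' @export
cross_validate <- function(data, scheme = c("flat", "tree"), alpha = NULL,
                           k_folds = 5L, K_max = 10L, seed = 1L,
                           train_ages = 1L, use_q = TRUE) {
  scheme <- match.arg(scheme)
  if (is.null(alpha)) alpha <- if (scheme == "flat") 0.005 else 5e-5
  is_bf <- !startsWith(data$meta$fluid, "non_bf:")
  split <- donor_kfold(data$meta$donor_id, k = k_folds, seed = seed,
                       strata = data$meta$fluid)
  fold_of <- split$fold[match(data$meta$donor_id, split$donor_id)]
  all_ages <- identical(train_ages, "all")
  asg <- NULL
  for (f in sort(unique(fold_of))) {
    tr <- fold_of != f & is_bf &
      (all_ages | data$meta$age_days %in% train_ages)
    te <- fold_of == f
    if (!any(te)) next
    train <- subset_spectra(data, which(tr))
    model <- if (scheme == "flat") {
      fit_flat_scheme(train, alpha = alpha, K_max = K_max,
                      k_folds = k_folds, seed = seed)
    } else {
      fit_tree_scheme(train, alpha = alpha, K_max = K_max,
                      k_folds = k_folds, seed = seed)
    }
    pred <- if (scheme == "flat") classify_flat(model, data$X[te, , drop = FALSE])
    else classify_tree(model, data$X[te, , drop = FALSE])
    if (!use_q) pred$predicted <- pred$candidate
    asg <- rbind(asg, data.frame(
      sample_id = data$meta$sample_id[te], fluid = data$meta$fluid[te],
      age_days = data$meta$age_days[te], fold = f,
      predicted = pred$predicted, q2 = pred$q2,
      q_threshold = pred$q_threshold))
  }
  strata <- sort(unique(asg$age_days))
  out <- lapply(strata, function(a) {
    i <- asg$age_days == a
    confusion_matrix(asg$fluid[i], asg$predicted[i])
  })
  names(out) <- .age_stratum_names(strata)
  attr(out, "assignments") <- asg
  out
}

#' Per-stratum accuracy summary of confusion matrices
#'
#' @param cms Named list of confusion matrices from [cross_validate()].
#' @return Data frame with stratum, n, n_correct, accuracy and
#'   outlier_rate (body-fluid rows only; interferent rows are summarized by
#'   their outlier rate).
#' @export
summarize_confusion <- function(cms) {
  do.call(rbind, lapply(names(cms), function(nm) {
    m <- cms[[nm]]
    bf <- intersect(rownames(m), fluid_labels())
    mb <- m[bf, , drop = FALSE]
    n <- sum(mb)
    corr <- sum(diag(m[bf, bf, drop = FALSE]))
    data.frame(stratum = nm, n = n, n_correct = corr,
               accuracy = if (n > 0) corr / n else NA_real_,
               outlier_rate = if (n > 0) sum(mb[, "OUTLIER"]) / n
               else NA_real_,
               non_bf_rejected = if ("non_bf" %in% rownames(m))
                 m["non_bf", "OUTLIER"] / sum(m["non_bf", ]) else NA_real_)
  }))
}

#' Compare the flat and tree discrimination schemes
#'
#' Runs three cross-validated schemes on identical donor splits: the flat
#' multi-class scheme trained on fresh spectra, the flat scheme trained on
#' all ages, and the dichotomous tree trained on fresh spectra. Reports
#' per-age accuracy and outlier rates plus the tree-minus-flat accuracy
#' difference.
#'
#' @param data Preprocessed [spectra_set()] with (possibly) several ages.
#' @param alpha_flat,alpha_tree Q significances for the two scheme types.
#' @param k_folds,K_max,seed As in [cross_validate()].
#' @return List with `summary` (long data frame over scheme x stratum),
#'   `difference` (tree minus fresh-flat accuracy per stratum) and the
#'   three confusion-matrix lists.
#' @export
compare_schemes <- function(data, alpha_flat = 0.005, alpha_tree = 5e-5,
                            k_folds = 5L, K_max = 10L, seed = 1L) {
  runs <- list(
    flat_fresh = cross_validate(data, "flat", alpha_flat, k_folds, K_max,
                                seed, train_ages = 1L),
    flat_aged = cross_validate(data, "flat", alpha_flat, k_folds, K_max,
                               seed, train_ages = "all"),
    tree = cross_validate(data, "tree", alpha_tree, k_folds, K_max, seed,
                          train_ages = 1L))
  summ <- do.call(rbind, lapply(names(runs), function(nm) {
    cbind(scheme = nm, summarize_confusion(runs[[nm]]))
  }))
  st <- summ[summ$scheme == "tree", c("stratum", "accuracy")]
  sf <- summ[summ$scheme == "flat_fresh", c("stratum", "accuracy")]
  diff <- merge(st, sf, by = "stratum", suffixes = c("_tree", "_flat"))
  diff$accuracy_gain <- diff$accuracy_tree - diff$accuracy_flat
  list(summary = summ, difference = diff, runs = runs)
}
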