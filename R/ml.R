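.tissue_features <- function(tissue) {
  switch(tissue,
    all = ntra_parameter_names(),
    fat = c("fat_N", "fat_mu", "fat_sigma", "fat_alpha"),
    connective = c("conn_N", "conn_mu", "conn_sigma"),
    muscle = c("musc_N", "musc_mu", "musc_sigma", "musc_alpha"),
    stop("unknown tissue: ", tissue, call. = FALSE))
}

#' Map canonical feature names to tissue groups
#' @param features Character vector of canonical parameter names.
#' @return Character vector of tissue names (`fat`, `connective`,
#'   `muscle`).
#' @export
feature_tissue_map <- function(features = ntra_parameter_names()) {
  tis <- ifelse(startsWith(features, "fat_"), "fat",
                ifelse(startsWith(features, "conn_"), "connective",
                       ifelse(startsWith(features, "musc_"), "muscle",
                              NA_character_)))
  if (anyNA(tis))
    stop("unmapped feature column(s): ",
         paste(features[is.na(tis)], collapse = ", "), call. = FALSE)
  setNames(tis, features)
}

#' Build a feature matrix for one tissue group and condition
#'
#' Selects the tissue-specific parameter columns (all 11, or the 4 fat,
#' 3 connective, or 4 muscle parameters) and the binary labels for one
#' condition; rows with a missing condition flag are dropped.
#'
#' @param cohort A cohort table.
#' @param tissue `"all"`, `"fat"`, `"connective"`, or `"muscle"`.
#' @param condition `"CHD"`, `"CVD"`, or `"CHF"`.
#' @return List with `X` (numeric matrix), `y` (logical), `tissue_map`,
#'   and `subject_id`.
#' @export
select_features <- function(cohort, tissue = "all",
                            condition = c("CHD", "CVD", "CHF")) {
  condition <- match.arg(condition)
  cols <- .tissue_features(tissue)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  flag <- cohort[[tolower(condition)]]
  keep <- !is.na(flag)
  X <- as.matrix(cohort[keep, cols, drop = FALSE])
  rownames(X) <- NULL
  list(X = X, y = as.logical(flag[keep]),
       tissue_map = feature_tissue_map(cols),
       subject_id = cohort$subject_id[keep])
}

new_metrics_report <- function(fields, algorithm, condition = NA_character_,
                               stratum = "total", extra = list()) {
  structure(c(list(algorithm = algorithm, condition = condition,
                   stratum = stratum), fields, extra),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("<metrics_report> %s / %s / %s\n",
           "  accuracy %.1f%% (max %.1f%%)  sens %.1f%%  spec %.1f%%  ",
           "prec %.1f%%  AUCROC %.3f\n"),
    x$algorithm, ifelse(is.na(x$condition), "-", x$condition), x$stratum,
    x$accuracy_mean, x$accuracy_max, x$sensitivity, x$specificity,
    x$precision, x$aucroc))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled subjects are
# dealt to folds round-robin, so fold sizes differ by at most one.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated ensemble classification
#'
#' Stratified k-fold cross-validation of one tree ensemble on a feature
#' matrix with class balancing by SMOTE. In the default `"fold_safe"`
#' mode each training portion is balanced separately, so no synthetic
#' point ever derives from a test subject; `"paper_faithful"` balances
#' the whole set once before splitting (the original study's protocol,
#' which leaks synthetic neighbours across folds); `"none"` disables
#' balancing. Accuracy is summarized per fold (mean and best fold);
#' sensitivity, specificity, recall, precision, and AUCROC are computed
#' on the pooled out-of-fold scores at the given threshold.
#'
#' @param X Numeric feature matrix.
#' @param y Logical labels.
#' @param algorithm `"RF"`, `"ADA-B"`, or `"GB"`.
#' @param k Number of folds (the study compared 8, 10, and 12 and
#'   settled on 12).
#' @param smote_mode `"fold_safe"`, `"paper_faithful"`, or `"none"`.
#' @param k_neighbors SMOTE neighbourhood size.
#' @param n_trees Trees / boosting rounds per model.
#' @param threshold Decision threshold for the confusion matrix.
#' @param seed Optional integer seed.
#' @return A `metrics_report` with `accuracy_mean`, `accuracy_max`,
#'   `sensitivity`, `specificity`, `recall`, `precision` (percent),
#'   `aucroc`, fold accounting (`n_folds`, `fold_sizes`,
#'   `skipped_folds`), and the pooled out-of-fold scores in `$pooled`.
#' @export
run_cv <- function(X, y, algorithm = c("RF", "ADA-B", "GB"), k = 12L,
                   smote_mode = c("fold_safe", "paper_faithful", "none"),
                   k_neighbors = 5L, n_trees = 100L, threshold = 0.5,
                   seed = NULL) {
  algorithm <- match.arg(algorithm)
  smote_mode <- match.arg(smote_mode)
  k <- as.integer(k)
  X <- as.matrix(X)
  y <- as.logical(y)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < k)
    stop("n (", nrow(X), ") must be at least the number of folds k (", k, ")",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (smote_mode == "paper_faithful") {
    bal <- smote_balance(X, y, k_neighbors = k_neighbors)
    X <- bal$X
    y <- bal$y
  }
  fold <- stratified_folds(y, k)
  fold_acc <- rep(NA_real_, k)
  fold_sizes <- tabulate(fold, nbins = k)
  skipped <- integer(0)
  pooled_y <- logical(0)
  pooled_s <- numeric(0)
  pooled_fold <- integer(0)
  for (f in seq_len(k)) {
    test <- fold == f
    if (length(unique(y[test])) < 2L) {
      warning("fold ", f, " has a single class in the test set; skipped",
              call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    if (smote_mode == "fold_safe") {
      bal <- smote_balance(Xtr, ytr, k_neighbors = k_neighbors)
      Xtr <- bal$X
      ytr <- bal$y
    }
    model <- train_ensemble(Xtr, ytr, algorithm, n_trees = n_trees)
    s <- predict_scores(model, X[test, , drop = FALSE])
    fold_acc[f] <- 100 * mean((s >= threshold) == y[test])
    pooled_y <- c(pooled_y, y[test])
    pooled_s <- c(pooled_s, s)
    pooled_fold <- c(pooled_fold, rep(f, sum(test)))
  }
  if (all(is.na(fold_acc)))
    stop("every fold was skipped; cannot evaluate", call. = FALSE)
  m <- compute_metrics(pooled_y, pooled_s, threshold)
  new_metrics_report(
    list(accuracy_mean = mean(fold_acc, na.rm = TRUE),
         accuracy_max = max(fold_acc, na.rm = TRUE),
         sensitivity = m$sensitivity, specificity = m$specificity,
         recall = m$recall, precision = m$precision, aucroc = m$aucroc),
    algorithm = algorithm,
    extra = list(k = k, n_folds = k, fold_sizes = fold_sizes,
                 skipped_folds = skipped, smote_mode = smote_mode,
                 pooled = data.frame(y = pooled_y, score = pooled_s,
                                     fold = pooled_fold)))
}

#' Tissue-grouped feature importance
#'
#' Sums a trained ensemble's per-feature importances within each tissue
#' group and rescales to percentages summing to 100.
#'
#' @param model A [train_ensemble] model (or a named importance vector
#'   summing to 1).
#' @param tissue_map Named character vector mapping feature names to
#'   tissues; defaults to the canonical mapping.
#' @return List with `fat_pct`, `connective_pct`, `muscle_pct`.
#' @export
tissue_importance <- function(model, tissue_map = NULL) {
  imp <- if (inherits(model, "ntra_ensemble")) feature_importances(model)
         else model
  stopifnot(is.numeric(imp), !is.null(names(imp)))
  if (is.null(tissue_map)) tissue_map <- feature_tissue_map(names(imp))
  unmapped <- setdiff(names(imp), names(tissue_map))
  if (length(unmapped))
    stop("unmapped feature column(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  groups <- tissue_map[names(imp)]
  tot <- sum(imp)
  pct <- function(tis) 100 * sum(imp[groups == tis]) / tot
  list(fat_pct = pct("fat"), connective_pct = pct("connective"),
       muscle_pct = pct("muscle"))
}

#' Default age strata
#'
#' The three age subgroups used for age-stratified classification:
#' 66-75, 76-83, and 84-98 years (inclusive endpoints).
#' @return List of `c(lower, upper)` pairs.
#' @export
default_age_bins <- function() {
  list(c(66L, 75L), c(76L, 83L), c(84L, 98L))
}

assign_age_bin <- function(age, bins = default_age_bins()) {
  out <- rep(NA_integer_, length(age))
  for (i in seq_along(bins))
    out[age >= bins[[i]][1] & age <= bins[[i]][2]] <- i
  # follow-up subjects who aged past the top stratum stay in it
  out[is.na(out) & age > bins[[length(bins)]][2]] <- length(bins)
  out
}

#' Age-stratified cross-validated classification
#'
#' Runs [run_cv] independently inside each age stratum.
#'
#' @param cohort A cohort table.
#' @param condition `"CHD"`, `"CVD"`, or `"CHF"`.
#' @param algorithm Ensemble name.
#' @param k Folds.
#' @param bins List of inclusive `c(lower, upper)` age intervals that
#'   partition the cohort's age range; defaults to [default_age_bins].
#' @param ... Passed to [run_cv].
#' @return A list of `metrics_report` objects (or `NULL` for an empty
#'   stratum), one per bin, named `"66-75"` etc.
#' @export
age_stratified_cv <- function(cohort, condition, algorithm = "RF", k = 12L,
                              bins = default_age_bins(), ...) {
  cohort <- as_cohort_table(cohort)
  bin_id <- assign_age_bin(cohort$age, bins)
  out <- vector("list", length(bins))
  names(out) <- vapply(bins, function(b) paste0(b[1], "-", b[2]), "")
  for (i in seq_along(bins)) {
    sub <- cohort[which(bin_id == i), , drop = FALSE]
    if (nrow(sub) == 0L) next
    fm <- select_features(sub, "all", condition)
    rep_i <- run_cv(fm$X, fm$y, algorithm, k = k, ...)
    rep_i$condition <- condition
    rep_i$stratum <- paste0("age ", names(out)[i])
    out[[i]] <- rep_i
  }
  out
}

#' Longitudinal incidence labels
#'
#' Builds the chronic-heart-failure incidence index from two
#' timepoints: label 0 for subjects free of the condition at both
#' waves, label 1 for subjects free at baseline but diagnosed at
#' follow-up. Subjects already positive at baseline are excluded, as
#' are subjects missing from the follow-up wave (with a warning) or
#' with a missing flag at either wave. Classification features are the
#' baseline profile parameters.
#'
#' @param cohort_t1,cohort_t2 Cohort tables for the two timepoints.
#' @param condition Condition to track (default `"CHF"`).
#' @return Data frame with `subject_id`, `label` (0/1, NA when
#'   excluded), `excluded`.
#' @export
incidence_labels <- function(cohort_t1, cohort_t2, condition = "CHF") {
  flag <- tolower(condition)
  ids <- cohort_t1$subject_id
  m <- match(ids, cohort_t2$subject_id)
  if (anyNA(m))
    warning(sum(is.na(m)), " baseline subject(s) missing at follow-up; ",
            "excluded", call. = FALSE)
  f1 <- cohort_t1[[flag]]
  f2 <- cohort_t2[[flag]][m]
  excluded <- is.na(m) | is.na(f1) | is.na(f2) | (!is.na(f1) & f1)
  label <- ifelse(excluded, NA_integer_, as.integer(f2))
  data.frame(subject_id = ids, label = label, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Full evaluation typology
#'
#' Orchestrates the five comparisons reported for each ensemble and
#' condition: total classification score, classification by tissue
#' type, tissue-grouped feature importance, classification by age
#' stratum, and (when a follow-up cohort is supplied) longitudinal
#' incidence prediction. Returns one nested, JSON-serializable report.
#'
#' @param cohort Baseline cohort table.
#' @param cohort_t2 Optional follow-up cohort table.
#' @param conditions Conditions to analyse.
#' @param algorithms Ensembles to run.
#' @param k Folds for every cross-validation.
#' @param smote_mode Balancing mode, see [run_cv].
#' @param n_trees Trees per ensemble.
#' @param age_bins Age strata for the by-age analysis.
#' @param seed Integer seed; the whole run is deterministic given the
#'   same cohort(s), configuration and seed.
#' @return Nested list with elements `config`, `total`, `by_tissue`,
#'   `tissue_importance`, `by_age`, and `longitudinal` (when
#'   applicable).
#' @export
full_typology <- function(cohort, cohort_t2 = NULL,
                          conditions = c("CHD", "CVD", "CHF"),
                          algorithms = c("RF", "ADA-B", "GB"),
                          k = 12L, smote_mode = "fold_safe",
                          n_trees = 100L, age_bins = default_age_bins(),
                          seed = 1L) {
  cohort <- as_cohort_table(cohort)
  set.seed(seed)
  strip <- function(r) r[c("algorithm", "condition", "stratum",
                           "accuracy_mean", "accuracy_max", "sensitivity",
                           "specificity", "recall", "precision", "aucroc",
                           "skipped_folds")]
  report <- list(config = list(conditions = conditions,
                               algorithms = algorithms, k = k,
                               smote_mode = smote_mode, n_trees = n_trees,
                               seed = seed))
  total <- list()
  by_tissue <- list()
  importance <- list()
  by_age <- list()
  for (cond in conditions) {
    for (alg in algorithms) {
      key <- paste(cond, alg, sep = ".")
      fm <- select_features(cohort, "all", cond)
      r <- run_cv(fm$X, fm$y, alg, k = k, smote_mode = smote_mode,
                  n_trees = n_trees)
      r$condition <- cond
      total[[key]] <- strip(r)
      for (tis in c("fat", "connective", "muscle")) {
        fmt <- select_features(cohort, tis, cond)
        rt <- run_cv(fmt$X, fmt$y, alg, k = k, smote_mode = smote_mode,
                     n_trees = n_trees)
        rt$condition <- cond
        rt$stratum <- tis
        by_tissue[[paste(key, tis, sep = ".")]] <- strip(rt)
      }
      bal <- smote_balance(fm$X, fm$y)
      model <- train_ensemble(bal$X, bal$y, alg, n_trees = n_trees)
      importance[[key]] <- tissue_importance(model)
      age_reports <- age_stratified_cv(cohort, cond, alg, k = k,
                                       bins = age_bins,
                                       smote_mode = smote_mode,
                                       n_trees = n_trees)
      by_age[[key]] <- lapply(age_reports, function(r)
        if (is.null(r)) NULL else strip(r))
    }
  }
  report$total <- total
  report$by_tissue <- by_tissue
  report$tissue_importance <- importance
  report$by_age <- by_age
  if (!is.null(cohort_t2)) {
    lab <- incidence_labels(cohort, cohort_t2)
    keep <- !lab$excluded
    idx <- match(lab$subject_id[keep], cohort$subject_id)
    X <- as.matrix(cohort[idx, ntra_parameter_names(), drop = FALSE])
    rownames(X) <- NULL
    y <- lab$label[keep] == 1L
    longitudinal <- list()
    for (alg in algorithms) {
      r <- run_cv(X, y, alg, k = k, smote_mode = smote_mode,
                  n_trees = n_trees)
      r$condition <- "CHF"
      r$stratum <- "incidence"
      longitudinal[[alg]] <- strip(r)
    }
    report$longitudinal <- longitudinal
  }
  report
}
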