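#' Build a junction feature table for family recognition
#'
#' Keeps the 3-way-junction records of a dataset and represents each as the
#' three counts of unpaired residues in the strands of the multiloop
#' (recomputed from the loop instance's dot-bracket) plus a binary label:
#' positive when the record comes from `positive_family`.
#'
#' @param records Tibble of dataset records.
#' @param positive_family Family accession defining the positive class.
#' @return A tibble with integer columns `u1`, `u2`, `u3` and factor column
#'   `label` (`positive`/`negative`), with attribute `positive_family`. A
#'   warning is issued (and the attribute `usable` set `FALSE`) when the
#'   positive family is absent.
#' @export
build_feature_table <- function(records, positive_family) {
  records <- tibble::as_tibble(records)
  records <- records[records$loop_order == 3L, , drop = FALSE]
  feats <- purrr::map(records$loop_db, function(db) {
    loops <- decompose_loops(parse_dotbracket(db), include_exterior = FALSE)
    loops <- loops[loops$order == 3L, , drop = FALSE]
    junction_features(loops[1L, ])
  })
  out <- tibble::tibble(
    u1 = purrr::map_int(feats, 1L),
    u2 = purrr::map_int(feats, 2L),
    u3 = purrr::map_int(feats, 3L),
    label = factor(ifelse(records$family_or_pdb == positive_family,
                          "positive", "negative"),
                   levels = c("negative", "positive"))
  )
  usable <- any(out$label == "positive")
  if (!usable) {
    warning("positive family '", positive_family,
            "' not present among 3-way junction records", call. = FALSE)
  }
  attr(out, "positive_family") <- positive_family
  attr(out, "usable") <- usable
  out
}

# Seeded stratified fold assignment: per class, shuffle then deal round-robin,
# so per-fold class counts differ by at most one.
.stratified_folds <- function(labels, k, seed = NULL) {
  assign_folds <- function() {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

# Group-aware fold assignment: every group lands wholly in one fold; groups
# are dealt to folds largest-first to balance fold sizes.
.group_folds <- function(groups, k, seed = NULL) {
  assign_folds <- function() {
    tab <- table(groups)
    gnames <- sample(names(tab))              # random tie order
    gnames <- gnames[order(-tab[gnames])]
    fold_of_group <- integer(0)
    load <- numeric(k)
    for (g in gnames) {
      f <- which.min(load)
      fold_of_group[g] <- f
      load[f] <- load[f] + tab[[g]]
    }
    unname(fold_of_group[as.character(groups)])
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

#' Macro-averaged F1 of a classification
#'
#' Unweighted mean of per-class F1 scores over all classes present in the
#' truth or the factor levels; a class with zero precision and recall
#' contributes 0.
#'
#' @param truth,pred Factors (or vectors) of class labels.
#' @return Numeric scalar in `[0, 1]`.
#' @export
macro_f1 <- function(truth, pred) {
  classes <- union(levels(factor(truth)), levels(factor(pred)))
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  mean(f1s)
}

# Fit/predict one classifier on numeric feature columns.
.fit_predict <- function(classifier, train, test) {
  feats <- setdiff(names(train), "label")
  switch(classifier,
    knn = class::knn(train[feats], test[feats], cl = train$label, k = 3L),
    decision_tree = {
      fit <- rpart::rpart(label ~ ., data = train, method = "class")
      predict(fit, test, type = "class")
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(label ~ ., data = train)
      predict(fit, test)
    },
    stop("unknown classifier '", classifier, "'", call. = FALSE)
  )
}

#' Stratified k-fold cross-validation with macro-F1 reporting
#'
#' Evaluates one or more classifiers on a junction feature table with
#' stratified k-fold cross-validation: folds preserve class proportions to
#' within one row, partition the table exactly, and are reproducible from
#' the seed. Reports the macro-averaged F1 per fold and the per-classifier
#' minimum, maximum, median and mean. With `groups` given, folds are
#' group-aware instead: all rows of a group go to the same fold (at the cost
#' of exact stratification).
#'
#' @param table Feature table from [build_feature_table()] (numeric feature
#'   columns plus `label`).
#' @param k Number of folds (default 5).
#' @param classifiers Character vector among `"knn"` (k = 3),
#'   `"decision_tree"`, `"naive_bayes"`.
#' @param seed Integer seed for the fold assignment and classifier fits.
#' @param groups Optional grouping vector (e.g. family accession per row) for
#'   group-based splitting.
#' @return An object of class `loop_cv`: list with `per_fold` (tibble:
#'   `classifier`, `fold`, `macro_f1`), `summary` (tibble: `classifier`,
#'   `min`, `max`, `median`, `mean`), `folds` (integer vector) and `k`.
#' @export
stratified_kfold_eval <- function(table, k = 5L,
                                  classifiers = c("knn", "decision_tree",
                                                  "naive_bayes"),
                                  seed = NULL, groups = NULL) {
  table <- tibble::as_tibble(table)
  stopifnot("label" %in% names(table))
  table$label <- factor(table$label)
  counts <- table(table$label)
  if (is.null(groups) && any(counts < k)) {
    stop("class '", names(counts)[which(counts < k)[1L]], "' has fewer than ",
         k, " rows", call. = FALSE)
  }
  fold <- if (is.null(groups)) .stratified_folds(table$label, k, seed)
          else .group_folds(groups, k, seed)
  fit_seed <- (if (is.null(seed)) 0L else seed) + 1L
  per_fold <- withr::with_seed(fit_seed, purrr::map_dfr(seq_len(k), function(f) {
    train <- table[fold != f, , drop = FALSE]
    test <- table[fold == f, , drop = FALSE]
    purrr::map_dfr(classifiers, function(clf) {
      pred <- .fit_predict(clf, train, test)
      tibble::tibble(classifier = clf, fold = f,
                     macro_f1 = macro_f1(test$label, pred))
    })
  }))
  summary <- per_fold |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(min = min(.data$macro_f1), max = max(.data$macro_f1),
                     median = stats::median(.data$macro_f1),
                     mean = mean(.data$macro_f1), .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary, folds = fold, k = k),
            class = "loop_cv")
}

#' @export
print.loop_cv <- function(x, ...) {
  cat("<loop_cv>", x$k, "fold cross-validation, macro-F1\n")
  print(x$summary)
  invisible(x)
}
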