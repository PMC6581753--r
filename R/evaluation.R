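#' Define a classification task over cohort groups
#'
#' Maps clinical group labels to class labels, supporting merged classes
#' (e.g. pooling CIS and RR into an "early" class). Groups absent from the
#' map are excluded from the task.
#'
#' @param name Task name.
#' @param class_map Named character vector: names are cohort group labels,
#'   values are class labels.
#' @return A `task_spec` with `classes` in sorted stable order.
#' @export
task_spec <- function(name, class_map) {
  stopifnot(is.character(class_map), !is.null(names(class_map)))
  structure(list(name = name, class_map = class_map,
                 classes = sort(unique(unname(class_map)))),
            class = "task_spec")
}

#' The standard MS task grid
#'
#' The five classification tasks of interest for an MS connectome cohort:
#' the four clinical courses, early vs progressive pooling, the two
#' HC-vs-patients contrasts, and the five-class problem including HC.
#'
#' @return Named list of [task_spec()] objects.
#' @export
ms_tasks <- function() {
  list(
    four_class = task_spec("CIS vs RR vs SP vs PP",
      c(CIS = "CIS", RR = "RR", SP = "SP", PP = "PP")),
    hc_vs_early = task_spec("HC vs (CIS+RR)",
      c(HC = "HC", CIS = "MS_early", RR = "MS_early")),
    hc_vs_progressive = task_spec("HC vs (SP+PP)",
      c(HC = "HC", SP = "MS_prog", PP = "MS_prog")),
    five_class = task_spec("HC vs SP vs PP vs RR vs CIS",
      c(HC = "HC", CIS = "CIS", RR = "RR", SP = "SP", PP = "PP")),
    early_vs_progressive = task_spec("(CIS+RR) vs (SP+PP)",
      c(CIS = "early", RR = "early", SP = "progressive", PP = "progressive")))
}

#' Stratified k-fold split
#'
#' Splits cohort records into k disjoint folds stratified by class. With
#' `by_subject = TRUE` (the default) the unit of splitting is the subject,
#' so all sessions of a subject land in the same fold and no longitudinal
#' information leaks between train and test; `by_subject = FALSE` splits
#' individual scans instead.
#'
#' @param records List of subject records.
#' @param classes Character vector of class labels, one per record.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param by_subject Keep each subject's sessions together.
#' @return List of k integer vectors indexing `records`; the folds are
#'   disjoint and exhaust the records.
#' @export
kfold_split <- function(records, classes, k = 3L, seed = 1L,
                        by_subject = TRUE) {
  stopifnot(k >= 2L, length(classes) == length(records))
  subj <- vapply(records, function(r) r$subject_id, character(1))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  folds <- vector("list", k)
  if (by_subject) {
    subj_class <- tapply(classes, subj, function(x) x[1L])
    for (cl in unique(subj_class)) {
      members <- names(subj_class)[subj_class == cl]
      if (length(members) < k)
        stop(sprintf("class '%s' has %d subjects, fewer than k = %d folds",
                     cl, length(members), k))
      members <- sample(members)
      assignment <- rep_len(seq_len(k), length(members))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], which(subj %in% members[assignment == f]))
    }
  } else {
    for (cl in unique(classes)) {
      members <- which(classes == cl)
      if (length(members) < k)
        stop(sprintf("class '%s' has %d records, fewer than k = %d folds",
                     cl, length(members), k))
      members <- sample(members)
      assignment <- rep_len(seq_len(k), length(members))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], members[assignment == f])
    }
  }
  lapply(folds, sort)
}

#' Macro-averaged precision, recall and F-measure
#'
#' Per-class precision, recall and F1 averaged with equal class weight;
#' undefined per-class ratios (empty prediction or truth for a class, or
#' zero precision + recall) are scored 0.
#'
#' @param y_true Integer true labels in `1..n_classes`.
#' @param y_pred Integer predicted labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return List with `precision`, `recall`, `f_measure` (macro averages)
#'   and `per_class` data frame.
#' @export
precision_recall_f1 <- function(y_true, y_pred, n_classes) {
  stopifnot(length(y_true) == length(y_pred))
  if (any(c(y_true, y_pred) < 1L) || any(c(y_true, y_pred) > n_classes))
    stop("labels must lie in 1..n_classes")
  prec <- rec <- f1 <- numeric(n_classes)
  for (c in seq_len(n_classes)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0) 2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
  }
  list(precision = mean(prec), recall = mean(rec), f_measure = mean(f1),
       per_class = data.frame(class = seq_len(n_classes), precision = prec,
                              recall = rec, f1 = f1))
}

#' Cross-validated classification experiment
#'
#' Runs the full pipeline for one cell of the experiment grid: threshold
#' every connectome at `tau`, build the renormalized adjacency (weighted or
#' binary) and the node features for `condition`, then k-fold train/test
#' with subject-level stratified folds, reporting macro precision, recall
#' and F-measure per fold with across-fold mean and standard deviation.
#'
#' @param cohort List of subject records.
#' @param task A [task_spec()].
#' @param condition Feature condition (see [build_feature_matrix()]).
#' @param weighted Use weighted graphs (adjacency and metric features).
#' @param tau Proportional threshold (default 0.35).
#' @param train_cfg A [train_config()].
#' @param k Number of folds (default 3).
#' @param k_channels Graph-convolution channels (default 100).
#' @param seed Seed for fold assignment and per-fold model initialization.
#' @param by_subject Subject-level folds (default TRUE).
#' @param labels_override Optional integer class labels (1..C) replacing the
#'   task-derived labels, e.g. a permutation for a null experiment.
#' @return A `cv_result`: per-fold scores, `mean` and `sd` of each score,
#'   and per-fold true/predicted labels.
#' @export
cross_validate <- function(cohort, task, condition = "identity",
                           weighted = TRUE, tau = 0.35,
                           train_cfg = train_config(), k = 3L,
                           k_channels = 100L, seed = 1L,
                           by_subject = TRUE, labels_override = NULL) {
  stopifnot(inherits(task, "task_spec"))
  groups <- vapply(cohort, function(r) r$group, character(1))
  keep <- which(groups %in% names(task$class_map))
  if (length(keep) == 0L) stop("no cohort record maps to a task class")
  cohort <- cohort[keep]
  classes <- unname(task$class_map[groups[keep]])
  y <- match(classes, task$classes)
  if (!is.null(labels_override)) {
    stopifnot(length(labels_override) == length(y))
    y <- as.integer(labels_override)
  }
  C <- length(task$classes)

  samples <- lapply(seq_along(cohort), function(i) {
    G <- threshold_graph(cohort[[i]]$matrix, tau)
    list(A_hat = prepare_adjacency(G, weighted = weighted),
         X = unclass(build_feature_matrix(G, condition, weighted = weighted)),
         label = y[i])
  })
  q <- nrow(samples[[1L]]$A_hat)
  d <- ncol(samples[[1L]]$X)

  folds <- kfold_split(cohort, classes, k = k, seed = seed,
                       by_subject = by_subject)
  fold_scores <- data.frame(fold = seq_len(k), precision = NA_real_,
                            recall = NA_real_, f_measure = NA_real_)
  predictions <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(samples), test_idx)
    model <- build_model(q, d, k = k_channels, n_classes = C,
                         seed = seed + f)
    cfg <- train_cfg
    cfg$seed <- train_cfg$seed + f
    fitted <- train_gcnn(model, samples[train_idx], cfg)
    y_pred <- vapply(test_idx, function(i) {
      which.max(predict_gcnn(fitted, samples[[i]]$A_hat, samples[[i]]$X))
    }, integer(1))
    sc <- precision_recall_f1(y[test_idx], y_pred, C)
    fold_scores[f, c("precision", "recall", "f_measure")] <-
      c(sc$precision, sc$recall, sc$f_measure)
    predictions[[f]] <- data.frame(index = test_idx, y_true = y[test_idx],
                                   y_pred = y_pred)
  }
  structure(list(task = task$name, condition = condition, weighted = weighted,
                 tau = tau, k = k, fold_scores = fold_scores,
                 mean = colMeans(fold_scores[, -1L]),
                 sd = apply(fold_scores[, -1L], 2L, stats::sd),
                 predictions = predictions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s | %s | %s | tau = %s>\n", x$task, x$condition,
              if (x$weighted) "weighted" else "unweighted", format(x$tau)))
  cat(sprintf("  F-Measure %.3f (+/- %.3f)  Precision %.3f (+/- %.3f)  Recall %.3f (+/- %.3f)\n",
              x$mean["f_measure"], x$sd["f_measure"],
              x$mean["precision"], x$sd["precision"],
              x$mean["recall"], x$sd["recall"]))
  invisible(x)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided two-sample rank-sum test. For combined sample sizes up to 20
#' the p-value comes from complete enumeration of all assignments of the
#' pooled observations to the two samples (exact even under ties); larger
#' samples use the normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `statistic` (the Mann-Whitney U of `sample_a`) and
#'   `p_value`.
#' @export
wilcoxon_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  n <- length(sample_a); m <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  if (n + m <= 20L) {
    combos <- utils::combn(n + m, n)
    U_all <- colSums(matrix(rk[combos], nrow = n)) - n * (n + 1) / 2
    p_lo <- mean(U_all <= U + 1e-9)
    p_hi <- mean(U_all >= U - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n * m / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
    sigma2 <- n * m / 12 * ((n + m + 1) - tie_term)
    z_num <- U - mu
    correction <- sign(z_num) * 0.5
    z <- (z_num - correction) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = U, p_value = p)
}
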