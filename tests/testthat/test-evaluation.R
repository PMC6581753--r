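fake_records <- function(n_subj_per_class, classes, n_sessions = 2L) {
  recs <- list()
  for (cl in classes) {
    for (s in seq_len(n_subj_per_class)) {
      for (sess in seq_len(n_sessions) - 1L) {
        recs[[length(recs) + 1L]] <- structure(
          list(subject_id = sprintf("%s_%02d", cl, s), group = cl,
               session = sess, matrix = NULL), class = "subject_record")
      }
    }
  }
  recs
}

test_that("stratified subject-level folds are disjoint, exhaustive and leak-free", {
  recs <- fake_records(3L, c("A", "B", "C"), n_sessions = 5L)
  classes <- vapply(recs, function(r) r$group, character(1))
  folds <- kfold_split(recs, classes, k = 3, seed = 1)
  expect_length(folds, 3L)
  expect_setequal(unlist(folds), seq_along(recs))
  expect_identical(sum(lengths(folds)), length(recs))
  # all sessions of a subject share one fold
  for (f in folds) {
    subj <- vapply(recs[f], function(r) r$subject_id, character(1))
    expect_true(all(table(subj) == 5L))
  }
  # 9 subjects, k = 3 -> 3 subjects per fold
  expect_true(all(lengths(folds) == 15L))
  # determinism
  expect_identical(folds, kfold_split(recs, classes, k = 3, seed = 1))
  expect_false(identical(folds, kfold_split(recs, classes, k = 3, seed = 2)))
})

test_that("a class with fewer subjects than folds is rejected", {
  recs <- fake_records(2L, c("A", "B"))
  classes <- vapply(recs, function(r) r$group, character(1))
  expect_error(kfold_split(recs, classes, k = 3), "fewer than k")
})

test_that("macro precision/recall/F match hand confusion-matrix arithmetic", {
  perfect <- precision_recall_f1(c(1, 2, 1, 2), c(1, 2, 1, 2), 2)
  expect_equal(perfect$f_measure, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  # truth (0,0,1,1), pred (0,1,1,1) in 1-based labels
  r <- precision_recall_f1(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  expect_equal(r$f_measure, (2 / 3 + 4 / 5) / 2, tolerance = 1e-12)

  # degenerate: everything predicted as class 1 on balanced truth
  r2 <- precision_recall_f1(c(1, 1, 2, 2), c(1, 1, 1, 1), 2)
  expect_equal(r2$f_measure, (2 / 3) / 2, tolerance = 1e-12)

  expect_error(precision_recall_f1(c(1, 3), c(1, 1), 2), "labels")
})

test_that("wilcoxon rank-sum matches its stated exact examples", {
  r <- wilcoxon_compare(c(1, 2, 3), c(10, 11, 12))
  expect_identical(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  self <- wilcoxon_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(self$p_value, 1)
  expect_error(wilcoxon_compare(numeric(0), 1), "non-empty")
})

test_that("exact p equals complete enumeration for all n = m <= 4 cases", {
  enum_p <- function(a, b) {
    n <- length(a); m <- length(b)
    pooled <- c(a, b)
    rk <- rank(pooled)
    U_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
    combos <- utils::combn(n + m, n)
    U_all <- apply(combos, 2, function(ix) sum(rk[ix]) - n * (n + 1) / 2)
    min(1, 2 * min(mean(U_all <= U_obs + 1e-9), mean(U_all >= U_obs - 1e-9)))
  }
  set.seed(19)
  for (n in 1:4) {
    for (rep in 1:20) {
      a <- sample(1:6, n, replace = TRUE)   # ties included
      b <- sample(1:6, n, replace = TRUE)
      expect_equal(wilcoxon_compare(a, b)$p_value, enum_p(a, b),
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("exact p agrees with wilcox.test when there are no ties", {
  set.seed(29)
  for (rep in 1:20) {
    a <- runif(sample(3:8, 1))
    b <- runif(sample(3:8, 1))
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(wilcoxon_compare(a, b)$p_value, ref, tolerance = 1e-12)
  }
})

test_that("large-sample p approximates wilcox.test's corrected normal p", {
  set.seed(31)
  a <- rnorm(15); b <- rnorm(18, 0.8)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(wilcoxon_compare(a, b)$p_value, ref, tolerance = 1e-10)
  # with ties
  a2 <- sample(1:5, 15, replace = TRUE); b2 <- sample(1:5, 18, replace = TRUE)
  ref2 <- stats::wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value
  expect_equal(wilcoxon_compare(a2, b2)$p_value, ref2, tolerance = 1e-10)
})

test_that("cross-validation on a tiny cohort is deterministic and leak-free", {
  cfg <- tiny_config(n_nodes = 16, n_subjects = 6L, n_sessions = 2L, seed = 3)
  co <- generate_cohort(cfg)
  task <- task_spec("HC vs RR vs SP", c(HC = "HC", RR = "RR", SP = "SP"))
  tc <- train_config(max_epochs = 30, patience = 30, seed = 4)
  r1 <- cross_validate(co, task, condition = "D", weighted = TRUE, tau = 0.5,
                       train_cfg = tc, k = 3, k_channels = 8, seed = 5)
  r2 <- cross_validate(co, task, condition = "D", weighted = TRUE, tau = 0.5,
                       train_cfg = tc, k = 3, k_channels = 8, seed = 5)
  expect_identical(r1$fold_scores, r2$fold_scores)
  expect_identical(r1$predictions, r2$predictions)
  # every record tested exactly once
  tested <- sort(unlist(lapply(r1$predictions, `[[`, "index")))
  expect_identical(tested, seq_along(co))
  # subjects never split across train/test (fold indices cover whole subjects)
  subj <- vapply(co, function(r) r$subject_id, character(1))
  for (p in r1$predictions) {
    expect_true(all(table(subj[p$index]) == 2L))
  }
  # scores within [0,1], mean within fold range
  expect_true(all(r1$fold_scores$f_measure >= 0 & r1$fold_scores$f_measure <= 1))
  expect_gte(r1$mean["f_measure"], min(r1$fold_scores$f_measure))
  expect_lte(r1$mean["f_measure"], max(r1$fold_scores$f_measure))
})

test_that("task specs map and exclude groups as declared", {
  tasks <- ms_tasks()
  expect_identical(tasks$hc_vs_early$classes, c("HC", "MS_early"))
  expect_identical(sort(names(tasks$five_class$class_map)),
                   sort(c("HC", "CIS", "RR", "SP", "PP")))
  # four-class task excludes HC records
  cfg <- tiny_config(n_nodes = 12, n_subjects = 3L, n_sessions = 1L)
  co <- generate_cohort(cfg)
  task <- task_spec("RR vs SP", c(RR = "RR", SP = "SP"))
  tc <- train_config(max_epochs = 5, patience = 5, seed = 1)
  r <- cross_validate(co, task, condition = "D", weighted = FALSE, tau = 0.5,
                      train_cfg = tc, k = 3, k_channels = 4, seed = 2)
  # predictions index into the task-filtered cohort: only RR and SP records
  n_in_task <- sum(vapply(co, function(x) x$group, character(1)) %in% c("RR", "SP"))
  tested <- unlist(lapply(r$predictions, `[[`, "index"))
  expect_identical(sort(tested), seq_len(n_in_task))
})
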