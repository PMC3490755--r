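# Cross-validation machinery, metric conventions, ROC/PR/AUC, aggregation
# modes and rank comparison.

test_that("fold splitting partitions chains with near-equal sizes", {
  keys <- sprintf("c%02d", 1:10)
  plan <- split_folds(keys, k = 5, seed = 3)
  expect_equal(sort(plan$chain_key), sort(keys))
  expect_equal(as.integer(table(plan$fold)), rep(2L, 5))
  expect_identical(plan, split_folds(keys, k = 5, seed = 3))
  plan11 <- split_folds(sprintf("c%02d", 1:11), k = 5, seed = 3)
  expect_equal(sort(as.integer(table(plan11$fold))), c(2L, 2L, 2L, 2L, 3L))
  expect_error(split_folds(keys[1:3], k = 5), "cannot make")
})

test_that("metrics follow the zero-positive-prediction conventions", {
  m <- compute_metrics(tp = 0, fp = 0, tn = 10, fn = 5)
  expect_equal(m$specificity, 1)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$fmeasure, 0)
  expect_equal(m$mcc, 0)
  perfect <- compute_metrics(tp = 50, fp = 0, tn = 50, fn = 0)
  expect_true(all(perfect[, c("specificity", "sensitivity", "fmeasure",
                              "mcc")] == 1))
  m2 <- compute_metrics(tp = 60, fp = 20, tn = 15, fn = 5)
  expect_equal(m2$mcc, 800 / sqrt(65 * 80 * 35 * 20), tolerance = 1e-12)
})

test_that("metrics match direct formula evaluation on random counts", {
  set.seed(71)
  tp <- sample(0:50, 1000, TRUE); fp <- sample(0:50, 1000, TRUE)
  tn <- sample(0:50, 1000, TRUE); fn <- sample(0:50, 1000, TRUE)
  m <- compute_metrics(tp, fp, tn, fn)
  for (i in sample(1000, 200)) {
    prec <- if (tp[i] + fp[i] == 0) 1 else tp[i] / (tp[i] + fp[i])
    rec <- if (tp[i] + fn[i] == 0) 0 else tp[i] / (tp[i] + fn[i])
    fme <- if (tp[i] + fp[i] == 0 || tp[i] + fn[i] == 0 || prec + rec == 0) 0
      else 2 * prec * rec / (prec + rec)
    den <- (tp[i] + fn[i]) * (tp[i] + fp[i]) * (tn[i] + fp[i]) * (tn[i] + fn[i])
    mcc <- if (den == 0) 0 else (tp[i] * tn[i] - fp[i] * fn[i]) / sqrt(den)
    expect_equal(m$specificity[i], prec)
    expect_equal(m$sensitivity[i], rec)
    expect_equal(m$fmeasure[i], fme)
    expect_equal(m$mcc[i], mcc)
  }
  expect_true(all(m$specificity >= 0 & m$specificity <= 1))
  expect_true(all(m$mcc >= -1 & m$mcc <= 1))
})

test_that("adding a correctly classified positive never hurts sensitivity or MCC", {
  set.seed(73)
  for (rep in 1:25) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    tn <- sample(1:20, 1); fn <- sample(1:20, 1)
    before <- compute_metrics(tp, fp, tn, fn)
    after <- compute_metrics(tp + 1, fp, tn, fn)
    expect_gte(after$sensitivity, before$sensitivity)
    expect_gte(after$mcc, before$mcc)
  }
})

test_that("AUC equals exhaustive positive-negative pair comparison", {
  out <- roc_pr_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(out$auc, 0.75)  # 3 wins of 4 pairs
  expect_equal(roc_pr_auc(c(5, 4, 2, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_pr_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(79)
  for (rep in 1:20) {
    n <- 30
    scores <- round(rnorm(n), 1)  # coarse: force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_pr_auc(scores, labels)$auc, mean(pairs))
  }
})

test_that("Mann-Whitney AUC equals the trapezoidal area under the swept ROC", {
  set.seed(83)
  for (rep in 1:20) {
    scores <- round(rnorm(40), 1)
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    out <- roc_pr_auc(scores, labels)
    trap <- sum(diff(out$roc$fpr) *
                  (utils::head(out$roc$tpr, -1) + utils::tail(out$roc$tpr, -1)) / 2)
    expect_equal(out$auc, trap, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(89)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, 0.3)
  ours <- roc_pr_auc(scores, labels)$auc
  ref <- suppressMessages(as.numeric(
    pROC::auc(labels, scores, levels = c(0, 1), direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("single-class label vectors are rejected", {
  expect_error(roc_pr_auc(1:5, rep(1, 5)), "both classes")
})

test_that("residue-based pooling and protein-based averaging diverge as expected", {
  counts <- tibble::tibble(
    fold = c(1L, 1L), chain_id = c("A", "B"),
    tp = c(5, 0), fp = c(5, 0), tn = c(10, 15), fn = c(0, 5)
  )
  res <- aggregate_residue_based(counts)
  expect_equal(res$overall$specificity, 0.5)
  expect_equal(res$overall$sensitivity, 0.5)
  prot <- aggregate_protein_based(counts)
  # protein B: zero positive predictions -> specificity 1, F = MCC = 0
  expect_equal(prot$overall$specificity, (0.5 + 1) / 2)
  expect_equal(prot$overall$sensitivity, (1 + 0) / 2)
  pp <- prot$per_protein
  expect_equal(pp$fmeasure[pp$chain_id == "B"], 0)
  expect_equal(pp$mcc[pp$chain_id == "B"], 0)
})

test_that("duplicating every protein's counts within a fold leaves residue metrics unchanged", {
  counts <- tibble::tibble(fold = 1L, chain_id = c("A", "B"),
                           tp = c(5, 2), fp = c(3, 1), tn = c(10, 12),
                           fn = c(2, 4))
  doubled <- dplyr::mutate(counts, dplyr::across(c(tp, fp, tn, fn), ~ .x * 2))
  r1 <- aggregate_residue_based(counts)$overall
  r2 <- aggregate_residue_based(doubled)$overall
  expect_equal(r1, r2)
})

test_that("aggregations coincide with one protein per fold", {
  counts <- tibble::tibble(fold = 1:3, chain_id = c("A", "B", "C"),
                           tp = c(4, 1, 3), fp = c(2, 0, 1),
                           tn = c(8, 9, 7), fn = c(1, 5, 2))
  res <- aggregate_residue_based(counts)$overall
  prot <- aggregate_protein_based(counts)$overall
  expect_equal(res$specificity, prot$specificity)
  expect_equal(res$sensitivity, prot$sensitivity)
  expect_equal(res$fmeasure, prot$fmeasure)
  expect_equal(res$mcc, prot$mcc)
})

test_that("per-protein AUC excludes single-class proteins from the average", {
  preds <- dplyr::bind_rows(
    tibble::tibble(fold = 1L, chain_id = "A", position = 1:6,
                   residue = "A", score = c(3, 2, 1, -1, -2, -3),
                   pred = c(1L, 1L, 1L, 0L, 0L, 0L),
                   label = c(1L, 1L, 0L, 1L, 0L, 0L)),
    tibble::tibble(fold = 1L, chain_id = "B", position = 1:4,
                   residue = "A", score = c(1, 0, -1, -2),
                   pred = c(1L, 0L, 0L, 0L), label = c(0L, 0L, 0L, 0L))
  )
  prot <- aggregate_protein_based(preds)
  expect_equal(prot$n_auc_excluded, 1L)
  auc_A <- roc_pr_auc(preds$score[preds$chain_id == "A"],
                      preds$label[preds$chain_id == "A"])$auc
  expect_equal(prot$per_fold$auc, auc_A)
})

test_that("cross-validation recovers planted signal and stays honest", {
  spec <- synthetic_spec(n_chains = 10, length_range = c(45, 55),
                         delta = 3, seed = 19)
  d <- withr::local_tempdir()
  gen_benchmark(spec, d)
  b <- load_benchmark(d)
  cfg <- encoding_config("PSSMSeq", 11)
  cv <- run_cv(b$dataset, b$profiles, cfg,
               train_config("svm", kernel_spec("rbf", gamma = 0.01)),
               k = 5, seed = 23)
  expect_gt(cv$residue$overall$auc, 0.9)
  # folds are chain-disjoint
  plan <- cv$fold_plan
  expect_equal(anyDuplicated(plan$chain_key), 0)
  expect_setequal(plan$chain_key, unique(b$dataset$chain_key))
  # every prediction's chain sits in that fold
  joined <- dplyr::left_join(cv$predictions, plan,
                             by = c(chain_id = "chain_key"))
  expect_equal(joined$fold.x, joined$fold.y)
  # determinism
  cv2 <- run_cv(b$dataset, b$profiles, cfg,
                train_config("svm", kernel_spec("rbf", gamma = 0.01)),
                k = 5, seed = 23)
  expect_equal(cv$predictions, cv2$predictions)
  expect_equal(glance(cv), glance(cv2))
})

test_that("shuffled labels give chance-level AUC", {
  spec <- synthetic_spec(n_chains = 10, length_range = c(45, 55),
                         delta = 0, seed = 29)
  d <- withr::local_tempdir()
  gen_benchmark(spec, d)
  b <- load_benchmark(d)
  cv <- run_cv(b$dataset, b$profiles, encoding_config("PSSMSeq", 11),
               train_config("nb", balance = FALSE), k = 5, seed = 31)
  expect_gt(cv$residue$overall$auc, 0.38)
  expect_lt(cv$residue$overall$auc, 0.62)
})

test_that("global pooling is available as an alternative ROC mode", {
  set.seed(97)
  preds <- tibble::tibble(
    fold = rep(1:2, each = 50), chain_id = rep(c("A", "B"), each = 50),
    position = rep(1:50, 2), residue = "A", score = rnorm(100),
    pred = rbinom(100, 1, 0.5), label = rbinom(100, 1, 0.5)
  )
  rf <- aggregate_residue_based(preds, pooling = "fold")
  rg <- aggregate_residue_based(preds, pooling = "global")
  expect_equal(rg$per_fold$auc[1], rg$per_fold$auc[2])
  expect_equal(rg$overall$auc, roc_pr_auc(preds$score, preds$label)$auc)
  expect_false(isTRUE(all.equal(rf$overall$auc, rg$overall$auc)))
})

test_that("tie-averaged ranks conserve rank mass and handle total ties", {
  tab <- tibble::tibble(method = c("m1", "m2", "m3", "m4"),
                        d1 = c(0.5, 0.7, 0.7, 0.9),
                        d2 = c(0.6, 0.6, 0.6, 0.6))
  rk <- average_ranks(tab)
  r1 <- rk$ranks$rank[rk$ranks$dataset == "d1"]
  expect_equal(sum(r1), 4 * 5 / 2)
  expect_equal(r1, c(4, 2.5, 2.5, 1))
  r2 <- rk$ranks$rank[rk$ranks$dataset == "d2"]
  expect_equal(r2, rep(2.5, 4))
  expect_equal(rk$average$average_rank[rk$average$method == "m4"],
               (1 + 2.5) / 2)
  expect_error(average_ranks(tibble::tibble(method = "m", d1 = NA_real_)),
               "missing")
})
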