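# Sequence-based k-fold cross-validation, confusion-count metrics with the
# degenerate-case conventions, ROC/PR/AUC, residue-based and protein-based
# aggregation, and tie-averaged rank comparison.

#' Split chains into cross-validation folds
#'
#' Whole protein chains are assigned to folds (sequence-based
#' cross-validation), guaranteeing train/test disjointness at the sequence
#' level. Chains are permuted with the seed and dealt round-robin, so fold
#' sizes differ by at most one.
#'
#' @param chain_keys Character vector of chain identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Tibble \code{chain_key}, \code{fold} with attributes \code{k} and
#'   \code{seed}.
#' @export
split_folds <- function(chain_keys, k = 5, seed = 1) {
  chain_keys <- unique(chain_keys)
  if (k > length(chain_keys)) {
    stop("cannot make ", k, " folds from ", length(chain_keys), " chains")
  }
  perm <- with_private_seed(seed, sample(chain_keys))
  structure(
    tibble::tibble(chain_key = perm,
                   fold = rep_len(seq_len(k), length(perm))) |>
      dplyr::arrange(.data$fold, .data$chain_key),
    k = k, seed = seed
  )
}

#' Confusion-count performance metrics
#'
#' Specificity here is the precision-style TP / (TP + FP) (the convention of
#' this framework, reported for the positive class); Sensitivity is the
#' recall TP / (TP + FN). Degenerate cases follow the stated conventions: a
#' predictor making zero positive predictions (TP + FP = 0) gets
#' Specificity 1, and any zero denominator in the F-measure or MCC yields 0.
#'
#' @param tp,fp,tn,fn Non-negative integer vectors (recycled).
#' @return Tibble with \code{tp,fp,tn,fn}, \code{specificity},
#'   \code{sensitivity}, \code{fpr}, \code{fmeasure}, \code{mcc}.
#' @export
#' @examples
#' compute_metrics(tp = 0, fp = 0, tn = 10, fn = 5)  # spec 1, F 0, MCC 0
compute_metrics <- function(tp, fp, tn, fn) {
  n <- max(length(tp), length(fp), length(tn), length(fn))
  tp <- rep_len(as.numeric(tp), n); fp <- rep_len(as.numeric(fp), n)
  tn <- rep_len(as.numeric(tn), n); fn <- rep_len(as.numeric(fn), n)
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative confusion counts")

  specificity <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
  sensitivity <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  fpr <- ifelse(fp + tn == 0, 0, fp / (fp + tn))
  fden <- specificity + sensitivity
  fmeasure <- ifelse(tp + fp == 0 | tp + fn == 0 | fden == 0, 0,
                     2 * specificity * sensitivity / fden)
  mden <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- ifelse(mden == 0, 0, (tp * tn - fp * fn) / sqrt(mden))
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 specificity = specificity, sensitivity = sensitivity,
                 fpr = fpr, fmeasure = fmeasure, mcc = mcc)
}

#' ROC curve, PR curve and AUC from ranking scores
#'
#' The ROC is swept over the distinct score values (ties grouped, so the
#' result does not depend on instance order); the AUC is the Mann-Whitney
#' statistic with half credit for tied scores, which equals the trapezoidal
#' area under the swept ROC. PR points are computed at the same thresholds.
#'
#' @param scores Numeric ranking scores (larger = more interface-like).
#' @param labels 0/1 truth labels; both classes must be present.
#' @return List with \code{roc} (tibble \code{threshold}, \code{fpr},
#'   \code{tpr}), \code{pr} (tibble \code{threshold}, \code{recall},
#'   \code{precision}) and scalar \code{auc}.
#' @export
roc_pr_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("roc_pr_auc: both classes must be present")

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  cum_tp <- cumsum(y)[last]
  cum_fp <- cumsum(1 - y)[last]
  thr <- s[last]

  roc <- tibble::tibble(threshold = c(Inf, thr),
                        fpr = c(0, cum_fp / n0),
                        tpr = c(0, cum_tp / n1))
  pr <- tibble::tibble(threshold = thr,
                       recall = cum_tp / n1,
                       precision = cum_tp / (cum_tp + cum_fp))
  # Mann-Whitney with tie half-credit via midranks
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = roc, pr = pr, auc = auc)
}

per_protein_counts <- function(predictions) {
  predictions |>
    dplyr::group_by(.data$fold, .data$chain_id) |>
    dplyr::summarise(
      tp = sum(.data$pred == 1L & .data$label == 1L),
      fp = sum(.data$pred == 1L & .data$label == 0L),
      tn = sum(.data$pred == 0L & .data$label == 0L),
      fn = sum(.data$pred == 0L & .data$label == 1L),
      .groups = "drop"
    )
}

new_rip_metrics <- function(aggregation, per_fold, overall, curves = NULL,
                            extra = list()) {
  structure(c(list(aggregation = aggregation, per_fold = per_fold,
                   overall = overall, curves = curves), extra),
            class = "rip_metrics")
}

#' Residue-based evaluation of fold predictions
#'
#' Within each fold, confusion counts are pooled over all residues of all
#' test proteins before metrics are computed; the reported overall values are
#' unweighted means over folds. Fold ROC/AUC are computed on the pooled
#' scores of the fold and averaged; \code{pooling = "global"} instead sweeps
#' a single ROC over all folds' scores.
#'
#' @param predictions Prediction tibble with a \code{fold} column (as
#'   produced by [run_cv()]), or a per-protein counts tibble with columns
#'   \code{fold}, \code{chain_id}, \code{tp}, \code{fp}, \code{tn}, \code{fn}
#'   (no ROC/AUC available in that case).
#' @param pooling \code{"fold"} (default) or \code{"global"} for the ROC/AUC.
#' @return A \code{rip_metrics} report.
#' @export
aggregate_residue_based <- function(predictions, pooling = c("fold", "global")) {
  pooling <- match.arg(pooling)
  have_scores <- "score" %in% names(predictions)
  counts <- if (have_scores) per_protein_counts(predictions) else
    tibble::as_tibble(predictions)
  if (nrow(counts) == 0) stop("no predictions to aggregate")

  fold_counts <- counts |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(dplyr::across(c("tp", "fp", "tn", "fn"), sum),
                     n_proteins = dplyr::n(), .groups = "drop")
  if (any(fold_counts$n_proteins == 0)) stop("empty fold")
  per_fold <- dplyr::bind_cols(
    fold = fold_counts$fold,
    compute_metrics(fold_counts$tp, fold_counts$fp, fold_counts$tn,
                    fold_counts$fn)
  )

  curves <- NULL
  if (have_scores) {
    if (pooling == "fold") {
      by_fold <- predictions |>
        dplyr::group_by(.data$fold) |>
        dplyr::group_map(function(d, g) {
          rp <- roc_pr_auc(d$score, d$label)
          list(fold = g$fold, rp = rp)
        })
      per_fold$auc <- vapply(by_fold, function(e) e$rp$auc, numeric(1))[
        match(per_fold$fold, vapply(by_fold, `[[`, numeric(1), "fold"))]
      curves <- list(
        roc = dplyr::bind_rows(lapply(by_fold, function(e)
          dplyr::mutate(e$rp$roc, fold = e$fold))),
        pr = dplyr::bind_rows(lapply(by_fold, function(e)
          dplyr::mutate(e$rp$pr, fold = e$fold)))
      )
    } else {
      rp <- roc_pr_auc(predictions$score, predictions$label)
      per_fold$auc <- rp$auc
      curves <- list(roc = dplyr::mutate(rp$roc, fold = NA_integer_),
                     pr = dplyr::mutate(rp$pr, fold = NA_integer_))
    }
  }

  metric_cols <- intersect(c("specificity", "sensitivity", "fpr", "fmeasure",
                             "mcc", "auc"), names(per_fold))
  overall <- per_fold |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean))
  new_rip_metrics("residue", per_fold, overall, curves,
                  extra = list(pooling = if (have_scores) pooling else NA))
}

#' Protein-based evaluation of fold predictions
#'
#' Metrics (with the degenerate-case conventions) are computed for each test
#' protein separately, averaged over the proteins of each fold, then averaged
#' over folds. Per-protein AUC is defined only for proteins carrying both
#' classes; single-class proteins are excluded from the fold's AUC average
#' and their count is reported.
#'
#' @inheritParams aggregate_residue_based
#' @return A \code{rip_metrics} report (field \code{n_auc_excluded} counts
#'   single-class proteins).
#' @export
aggregate_protein_based <- function(predictions) {
  have_scores <- "score" %in% names(predictions)
  counts <- if (have_scores) per_protein_counts(predictions) else
    tibble::as_tibble(predictions)
  if (nrow(counts) == 0) stop("no predictions to aggregate")

  per_protein <- dplyr::bind_cols(
    counts[, c("fold", "chain_id")],
    compute_metrics(counts$tp, counts$fp, counts$tn, counts$fn)
  )

  n_auc_excluded <- 0L
  if (have_scores) {
    auc_tbl <- predictions |>
      dplyr::group_by(.data$fold, .data$chain_id) |>
      dplyr::summarise(
        auc = if (length(unique(.data$label)) == 2)
          roc_pr_auc(.data$score, .data$label)$auc else NA_real_,
        .groups = "drop"
      )
    per_protein <- dplyr::left_join(per_protein, auc_tbl,
                                    by = c("fold", "chain_id"))
    n_auc_excluded <- sum(is.na(per_protein$auc))
  }

  metric_cols <- intersect(c("specificity", "sensitivity", "fpr", "fmeasure",
                             "mcc", "auc"), names(per_protein))
  per_fold <- per_protein |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE)),
      n_proteins = dplyr::n(), .groups = "drop"
    )
  overall <- per_fold |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean))
  new_rip_metrics("protein", per_fold, overall,
                  extra = list(per_protein = per_protein,
                               n_auc_excluded = n_auc_excluded))
}

#' @export
print.rip_metrics <- function(x, ...) {
  cat("<rip_metrics> ", x$aggregation, "-based evaluation, ",
      nrow(x$per_fold), " fold(s)\n", sep = "")
  print(x$overall)
  invisible(x)
}

#' @rdname tidy.rip_metrics
#' @export
glance.rip_metrics <- function(x, ...) x$overall

#' Tidy / summarise a metrics report
#'
#' \code{tidy()} returns the per-fold metric rows; \code{glance()} the
#' fold-averaged overall row.
#'
#' @param x A \code{rip_metrics}.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rip_metrics <- function(x, ...) x$per_fold

#' Plot ROC and PR curves of a metrics report
#'
#' @param object A \code{rip_metrics} with curves (residue-based report from
#'   score-bearing predictions).
#' @param which \code{"roc"} or \code{"pr"}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rip_metrics <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (is.null(object$curves)) stop("this report carries no curves")
  if (which == "roc") {
    df <- object$curves$roc
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                          group = .data$fold,
                                          colour = factor(.data$fold))) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    colour = "Fold", title = "ROC")
  } else {
    df <- object$curves$pr
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$recall,
                                          y = .data$precision,
                                          group = .data$fold,
                                          colour = factor(.data$fold))) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Recall (Sensitivity)",
                    y = "Precision (Specificity)",
                    colour = "Fold", title = "Precision-Recall")
  }
  p + ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Sequence-based k-fold cross-validation
#'
#' Chains are split into k folds; for each fold a classifier is trained on
#' the residues of all other folds' chains (with undersampling applied to the
#' training instances only, when configured) and every residue of the test
#' fold's chains is scored. Test instances are never balanced. Returns both
#' residue-based and protein-based reports.
#'
#' @param dataset A \code{rip_dataset}.
#' @param profiles Named list of \code{rip_pssm} profiles by chain key.
#' @param encoding An [encoding_config()].
#' @param config A [train_config()].
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment and (derived per fold) balancing.
#' @return An object of class \code{rip_cv}: list with \code{residue} and
#'   \code{protein} (\code{rip_metrics}), \code{predictions} (tibble with
#'   \code{fold} column), \code{fold_plan}, \code{encoding}, \code{config},
#'   \code{seed}.
#' @export
run_cv <- function(dataset, profiles = NULL, encoding = encoding_config(),
                   config = train_config(), k = 5, seed = 1) {
  stopifnot(inherits(dataset, "rip_dataset"))
  plan <- split_folds(unique(dataset$chain_key), k = k, seed = seed)
  feats <- encode_dataset(dataset, profiles, encoding)
  fold_of <- plan$fold[match(feats$meta$chain_key, plan$chain_key)]

  preds <- lapply(seq_len(k), function(f) {
    train_keys <- plan$chain_key[plan$fold != f]
    test_keys <- plan$chain_key[plan$fold == f]
    stopifnot(length(intersect(train_keys, test_keys)) == 0)
    tr <- subset_features(feats, fold_of != f)
    te <- subset_features(feats, fold_of == f)
    if (length(unique(tr$meta$label)) < 2) {
      stop("fold ", f, ": training data contain a single class")
    }
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_classifier(tr, cfg)
    dplyr::mutate(predict(model, te), fold = f)
  })
  predictions <- dplyr::bind_rows(preds)

  structure(
    list(residue = aggregate_residue_based(predictions),
         protein = aggregate_protein_based(predictions),
         predictions = predictions, fold_plan = plan,
         encoding = encoding, config = config, seed = seed),
    class = "rip_cv"
  )
}

#' @export
print.rip_cv <- function(x, ...) {
  cat("<rip_cv> ", x$encoding$encoding, " + ", x$config$algorithm,
      if (x$config$algorithm == "svm") paste0("/", x$config$kernel$family),
      ", ", max(x$fold_plan$fold), "-fold sequence-based CV\n", sep = "")
  cat("residue-based overall:\n"); print(x$residue$overall)
  cat("protein-based overall:\n"); print(x$protein$overall)
  invisible(x)
}

#' @rdname tidy.rip_cv
#' @export
glance.rip_cv <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$residue$overall, aggregation = "residue"),
    dplyr::mutate(x$protein$overall, aggregation = "protein")
  ) |> dplyr::relocate("aggregation")
}

#' Tidy / summarise a cross-validation result
#'
#' \code{tidy()} stacks the per-fold rows of both aggregations;
#' \code{glance()} returns one overall row per aggregation.
#'
#' @param x A \code{rip_cv}.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rip_cv <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$residue$per_fold, aggregation = "residue"),
    dplyr::mutate(x$protein$per_fold, aggregation = "protein")
  ) |> dplyr::relocate("aggregation")
}

#' Tie-averaged rank comparison of methods across datasets
#'
#' For each dataset, methods are ranked by descending score (rank 1 = best);
#' tied scores receive the mean of the rank positions they span. The average
#' rank of each method across datasets summarises the comparison.
#'
#' @param score_table Wide tibble/data frame with a \code{method} column and
#'   one numeric column per dataset, or a numeric matrix with methods as
#'   rownames and datasets as columns.
#' @return A \code{rip_ranks}: list with \code{ranks} (long tibble
#'   \code{method}, \code{dataset}, \code{score}, \code{rank}) and
#'   \code{average} (tibble \code{method}, \code{average_rank}, sorted best
#'   first).
#' @export
average_ranks <- function(score_table) {
  if (is.matrix(score_table)) {
    stopifnot(!is.null(rownames(score_table)))
    score_table <- tibble::as_tibble(score_table, rownames = "method")
  }
  stopifnot("method" %in% names(score_table))
  long <- tidyr::pivot_longer(tibble::as_tibble(score_table), -"method",
                              names_to = "dataset", values_to = "score")
  if (anyNA(long$score)) stop("score table has missing cells")
  long <- long |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(rank = rank(-.data$score, ties.method = "average")) |>
    dplyr::ungroup()
  avg <- long |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(average_rank = mean(.data$rank), .groups = "drop") |>
    dplyr::arrange(.data$average_rank)
  structure(list(ranks = long, average = avg), class = "rip_ranks")
}

#' @export
print.rip_ranks <- function(x, ...) {
  cat("<rip_ranks> ", dplyr::n_distinct(x$ranks$method), " methods over ",
      dplyr::n_distinct(x$ranks$dataset), " datasets\n", sep = "")
  print(x$average)
  invisible(x)
}

#' @rdname average_ranks
#' @param x A \code{rip_ranks}.
#' @param ... Unused.
#' @export
tidy.rip_ranks <- function(x, ...) x$ranks
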