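#' @title Performance-grouped classification experiments
#' @name experiments
#' @description
#' The five train/test designs used to probe how task performance shapes
#' cognitive-load classification, executed over a feature table holding one
#' rest and one task vector per subject:
#' * E1 — first 20 subjects train, last 16 test;
#' * E2 — first 20 subjects train, all 36 predicted (deliberately
#'   non-disjoint, for the all-subject summary table);
#' * E3 — BAD performers (X <= 10) train, GOOD performers test;
#' * E4 — the 10 lowest-X GOOD performers ("Average_GOOD") train, the
#'   remaining 16 GOOD performers test;
#' * E5 — first 18 subjects train, all 36 predicted (deliberately
#'   non-disjoint, the balanced-training design).
#' "First N" means ascending subject-ID order. Both condition vectors of a
#' subject always stay on the same side of a split.
NULL

#' Build a named train/test experiment design
#'
#' @param name One of `"E1"`..`"E5"`.
#' @param manifest Data frame with `subject_id`, `X` (and optionally
#'   `group`; derived by the X <= 10 rule if absent).
#' @return Object of class `experiment_design`: list with `name`,
#'   `train_subject_ids`, `test_subject_ids`, `disjoint`.
#' @export
make_design <- function(name, manifest) {
  if (is.null(manifest$group)) manifest$group <- ifelse(manifest$X <= 10, "BAD", "GOOD")
  ids <- manifest$subject_id[order(manifest$subject_id)]
  m <- manifest[order(manifest$subject_id), ]
  good <- m[m$group == "GOOD", ]
  good <- good[order(good$X, good$subject_id), ]
  d <- switch(name,
    E1 = list(train = utils::head(ids, 20), test = utils::tail(ids, length(ids) - 20)),
    E2 = list(train = utils::head(ids, 20), test = ids),
    E3 = list(train = m$subject_id[m$group == "BAD"],
              test = m$subject_id[m$group == "GOOD"]),
    E4 = list(train = utils::head(good$subject_id, 10),
              test = utils::tail(good$subject_id, nrow(good) - 10)),
    E5 = list(train = utils::head(ids, 18), test = ids),
    stop("unknown design name: ", name, call. = FALSE))
  structure(list(name = name,
                 train_subject_ids = d$train,
                 test_subject_ids = d$test,
                 disjoint = !name %in% c("E2", "E5")),
            class = "experiment_design")
}

# Split a feature table into a labeled matrix (rest -> class_1, task ->
# class_2) restricted to the given subjects.
.labeled_matrix <- function(features, subject_ids) {
  rows <- features[features$subject_id %in% subject_ids, , drop = FALSE]
  missing <- setdiff(subject_ids, rows$subject_id)
  if (length(missing) > 0L)
    stop("no feature vectors for subject(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cnt <- table(rows$subject_id, rows$condition)
  if (!all(dim(cnt) == c(length(subject_ids), 2L)) || !all(cnt == 1L))
    stop("each subject needs exactly one rest and one task vector", call. = FALSE)
  list(x = as.matrix(rows[, feature_layout(), drop = FALSE]),
       y = ifelse(rows$condition == "task", "class_2", "class_1"),
       subject_id = rows$subject_id,
       condition = rows$condition)
}

.comment_for <- function(pred_rest, pred_task) {
  if (pred_rest == "class_1" && pred_task == "class_2") "correct"
  else if (pred_rest == "class_2" && pred_task == "class_1") "Reversed"
  else if (pred_rest == "class_1") "Both_as_class_1"
  else "Both_as_class_2"
}

#' Run one experiment design
#'
#' Trains the polynomial-kernel SVM on the design's training subjects (both
#' conditions) and predicts the rest and task vectors of every test
#' subject.
#'
#' @param design An `experiment_design` from [make_design()].
#' @param features Feature table (one rest and one task row per subject).
#' @param manifest Subject manifest (`subject_id`, `X`, `group`).
#' @param order,C SVM hyper-parameters.
#' @return A prediction table: data frame with `subject_id`, `X`, `group`,
#'   `pred_rest`, `pred_task`, `comment`.
#' @export
run_experiment <- function(design, features, manifest, order = 4L, C = 1) {
  stopifnot(inherits(design, "experiment_design"))
  .check_feature_table(features)
  tr <- .labeled_matrix(features, design$train_subject_ids)
  model <- train_svm(tr$x, tr$y, order = order, C = C)
  test_ids <- design$test_subject_ids
  if (length(test_ids) == 0L) {
    return(data.frame(subject_id = character(0), X = numeric(0),
                      group = character(0), pred_rest = character(0),
                      pred_task = character(0), comment = character(0),
                      stringsAsFactors = FALSE))
  }
  te <- .labeled_matrix(features, test_ids)
  pred <- predict(model, te$x)
  rest_pred <- pred[te$condition == "rest"][match(test_ids, te$subject_id[te$condition == "rest"])]
  task_pred <- pred[te$condition == "task"][match(test_ids, te$subject_id[te$condition == "task"])]
  mi <- match(test_ids, manifest$subject_id)
  out <- data.frame(subject_id = test_ids,
                    X = manifest$X[mi],
                    group = manifest$group[mi],
                    pred_rest = rest_pred,
                    pred_task = task_pred,
                    stringsAsFactors = FALSE)
  out$comment <- mapply(.comment_for, out$pred_rest, out$pred_task)
  out
}

#' Classification accuracy across polynomial orders
#'
#' @param features,design,manifest,C As in [run_experiment()].
#' @param orders Integer vector of kernel orders to try.
#' @return Data frame with `order` and `overall_accuracy` (percent).
#' @export
order_sweep <- function(features, design, manifest, orders = 1:6, C = 1) {
  if (length(orders) < 1L) stop("need at least one order", call. = FALSE)
  acc <- vapply(orders, function(o) {
    tab <- run_experiment(design, features, manifest, order = o, C = C)
    evaluate_prediction_table(tab)$overall_accuracy
  }, numeric(1))
  data.frame(order = orders, overall_accuracy = acc)
}

# --- small self-contained baselines (no tree/NB library in the supported
# environment) -------------------------------------------------------------

.nb_train <- function(x, y) {
  lv <- sort(unique(y))
  lapply(stats::setNames(lv, lv), function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xc)
    va <- apply(xc, 2, stats::var)
    va <- pmax(va, 1e-9 * max(va, 1))   # variance floor
    list(mu = mu, va = va, prior = mean(y == cl))
  })
}

.nb_predict <- function(fit, x) {
  ll <- sapply(fit, function(p) {
    rowSums(sweep(-(sweep(x, 2, p$mu)^2), 2, 2 * p$va, "/") -
              matrix(log(2 * pi * p$va), nrow(x), ncol(x), byrow = TRUE) / 2) +
      log(p$prior)
  })
  names(fit)[max.col(ll, ties.method = "first")]
}

# Greedy Gini CART on axis-aligned splits, depth-capped.
.tree_train <- function(x, y, depth = 5L, min_n = 2L) {
  gini <- function(yy) { p <- table(yy) / length(yy); 1 - sum(p^2) }
  grow <- function(idx, d) {
    yy <- y[idx]
    maj <- names(sort(table(yy), decreasing = TRUE))[1]
    if (d >= depth || length(idx) < min_n || length(unique(yy)) == 1L)
      return(list(leaf = TRUE, label = maj))
    best <- NULL; best_imp <- gini(yy) - 1e-9
    for (j in seq_len(ncol(x))) {
      v <- x[idx, j]
      cuts <- unique(stats::quantile(v, probs = seq(0.1, 0.9, 0.2), names = FALSE))
      for (cut in cuts) {
        l <- idx[v <= cut]; r <- idx[v > cut]
        if (length(l) == 0L || length(r) == 0L) next
        imp <- (length(l) * gini(y[l]) + length(r) * gini(y[r])) / length(idx)
        if (imp < best_imp) { best_imp <- imp; best <- list(j = j, cut = cut) }
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, label = maj))
    v <- x[idx, best$j]
    list(leaf = FALSE, j = best$j, cut = best$cut,
         left = grow(idx[v <= best$cut], d + 1L),
         right = grow(idx[v > best$cut], d + 1L))
  }
  grow(seq_len(nrow(x)), 0L)
}

.tree_predict <- function(node, x) {
  apply(x, 1, function(row) {
    nd <- node
    while (!nd$leaf) nd <- if (row[nd$j] <= nd$cut) nd$left else nd$right
    nd$label
  })
}

#' Compare the SVM against standard baseline classifiers
#'
#' Fits linear discriminant analysis (`MASS::lda`), the polynomial SVM,
#' 1-nearest-neighbour (`FNN::knn`), a depth-capped Gini decision tree and
#' Gaussian naive Bayes on the design's training subjects and reports the
#' subject-level both-class and overall accuracies of each on the test
#' subjects.
#'
#' @inheritParams run_experiment
#' @return Data frame with one row per classifier (`LDA`, `SVM`, `kNN`,
#'   `Tree`, `NaiveBayes`) and columns `both_class_accuracy`,
#'   `overall_accuracy` (percent).
#' @export
baseline_comparison <- function(design, features, manifest, order = 4L, C = 1) {
  tr <- .labeled_matrix(features, design$train_subject_ids)
  te <- .labeled_matrix(features, design$test_subject_ids)
  keep <- which(apply(tr$x, 2, stats::sd) > 0)
  xtr <- scale(tr$x[, keep, drop = FALSE])
  xte <- scale(te$x[, keep, drop = FALSE],
               center = attr(xtr, "scaled:center"),
               scale = attr(xtr, "scaled:scale"))
  svm_model <- train_svm(tr$x, tr$y, order = order, C = C)
  preds <- list(
    LDA = {
      fit <- suppressWarnings(MASS::lda(xtr, grouping = factor(tr$y)))
      as.character(stats::predict(fit, xte)$class)
    },
    SVM = predict(svm_model, te$x),
    kNN = as.character(FNN::knn(xtr, xte, factor(tr$y), k = 1)),
    Tree = {
      fit <- .tree_train(xtr, tr$y)
      unname(.tree_predict(fit, xte))
    },
    NaiveBayes = .nb_predict(.nb_train(xtr, tr$y), xte))
  rows <- lapply(names(preds), function(nm) {
    tab <- data.frame(subject_id = te$subject_id, condition = te$condition,
                      pred = preds[[nm]], stringsAsFactors = FALSE)
    rest <- tab[tab$condition == "rest", ]
    task <- tab[tab$condition == "task", ]
    task <- task[match(rest$subject_id, task$subject_id), ]
    pt <- data.frame(subject_id = rest$subject_id, X = NA_real_,
                     pred_rest = rest$pred, pred_task = task$pred,
                     stringsAsFactors = FALSE)
    ev <- evaluate_prediction_table(pt)
    data.frame(classifier = nm,
               both_class_accuracy = ev$both_class_accuracy,
               overall_accuracy = ev$overall_accuracy)
  })
  do.call(rbind, rows)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", x$name, ": ", length(x$train_subject_ids),
      " train / ", length(x$test_subject_ids), " test subjects",
      if (!x$disjoint) " (non-disjoint by design)", "\n", sep = "")
  invisible(x)
}
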