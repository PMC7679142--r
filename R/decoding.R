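#' @importFrom nnet nnet class.ind
NULL

# Fit the configured classifier on (Xtr, ytr) and predict classes for Xte.
# classifier "mlp": single-hidden-layer network (nnet); "rf": random
# forest (ranger, 100 trees).
fit_predict <- function(Xtr, ytr, Xte, classifier = "mlp", hidden = 16,
                        maxit = 150, decay = 0.1, num_trees = 100) {
  classes <- sort(unique(ytr))
  if (length(classes) < 2) stop("training data must contain >= 2 classes")
  if (classifier == "mlp") {
    if (length(classes) == 2) {
      fit <- nnet::nnet(x = Xtr, y = as.numeric(ytr == classes[2]),
                        size = hidden, decay = decay, maxit = maxit,
                        entropy = TRUE, trace = FALSE, MaxNWts = 1e5)
      pr <- as.numeric(stats::predict(fit, Xte))
      classes[(pr > 0.5) + 1]
    } else {
      fit <- nnet::nnet(x = Xtr, y = nnet::class.ind(factor(ytr)),
                        size = hidden, decay = decay, maxit = maxit,
                        softmax = TRUE, trace = FALSE, MaxNWts = 1e5)
      pr <- stats::predict(fit, Xte)
      as.integer(colnames(pr)[max.col(pr)])
    }
  } else if (classifier == "rf") {
    df <- data.frame(Xtr)
    df$.y <- factor(ytr, levels = classes)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = num_trees,
                          seed = sample.int(.Machine$integer.max, 1))
    te <- data.frame(Xte)
    colnames(te) <- colnames(df)[seq_len(ncol(Xte))]
    as.integer(as.character(stats::predict(fit, te)$predictions))
  } else stop("unknown classifier: ", classifier)
}

# One stratified k-fold CV pass with fold-wise z-scoring (scaling
# parameters estimated on the training folds only). Returns mean held-out
# accuracy.
cv_accuracy <- function(X, y, folds = 5, classifier = "mlp", ...) {
  fold_id <- stratified_folds(y, folds)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    Xtr <- zscore_cols(X[tr, , drop = FALSE], mu, sdv)
    Xte <- zscore_cols(X[!tr, , drop = FALSE], mu, sdv)
    pred <- fit_predict(Xtr, y[tr], Xte, classifier, ...)
    acc[f] <- mean(pred == y[!tr])
  }
  mean(acc)
}

#' Single-region population decoding
#'
#' For each of `repeats` iterations: draw `n_neurons` without replacement
#' (`n_draws` independent draws per iteration), balance classes by random
#' under-sampling, z-score features (scaling fit on training folds only),
#' and run stratified k-fold cross-validation with a multi-layer
#' perceptron. The decoder accuracy Da is the mean held-out accuracy over
#' all iterations. A shuffled-label control repeats the identical
#' procedure on permuted class vectors.
#'
#' @param data a `labeled_dataset` (see [build_labels()]).
#' @param n_neurons neurons per draw (default: all).
#' @param n_draws random draws per repeat (default 1).
#' @param repeats iterations of the whole procedure (default 40).
#' @param folds CV folds (default 5).
#' @param classifier "mlp" (default) or "rf".
#' @param hidden,maxit,decay MLP hyperparameters (single hidden layer of
#'   `hidden` logistic units, weight decay `decay`, at most `maxit`
#'   optimizer iterations).
#' @param shuffle if TRUE the class vector is permuted each iteration
#'   (chance control); Da then estimates chance level.
#' @param shuffle_control if TRUE, also run the shuffled-label control
#'   alongside and store its accuracies.
#' @param seed integer seed.
#' @return object of class `decoding_result`: list with `da` (mean
#'   accuracy), `accuracies` (per iteration), `shuffled` (control
#'   accuracies or NULL), `task`, `spec`.
#' @export
decode_single_region <- function(data, n_neurons = NULL, n_draws = 1,
                                 repeats = 40, folds = 5,
                                 classifier = "mlp", hidden = 16,
                                 maxit = 150, decay = 0.1,
                                 shuffle = FALSE, shuffle_control = FALSE,
                                 seed = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (data$empty || length(unique(data$y)) < 2)
    stop("dataset must contain at least two classes")
  if (is.null(n_neurons)) n_neurons <- ncol(data$X)
  if (n_neurons > ncol(data$X))
    stop("n_neurons exceeds available neurons (", ncol(data$X), ")")
  set.seed(seed)
  acc <- numeric(0)
  acc_sh <- numeric(0)
  for (r in seq_len(repeats)) {
    for (d in seq_len(n_draws)) {
      cols <- sort(sample.int(ncol(data$X), n_neurons))
      bal <- balance_undersample(data)
      X <- bal$X[, cols, drop = FALSE]
      y <- if (shuffle) sample(bal$y) else bal$y
      acc <- c(acc, cv_accuracy(X, y, folds, classifier, hidden = hidden,
                                maxit = maxit, decay = decay))
      if (shuffle_control)
        acc_sh <- c(acc_sh, cv_accuracy(X, sample(y), folds, classifier,
                                        hidden = hidden, maxit = maxit,
                                        decay = decay))
    }
  }
  structure(list(da = mean(acc), accuracies = acc,
                 shuffled = if (shuffle_control) acc_sh else NULL,
                 task = data$task,
                 spec = list(n_neurons = n_neurons, n_draws = n_draws,
                             repeats = repeats, folds = folds,
                             classifier = classifier, shuffle = shuffle,
                             seed = seed)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("Decoding (task ", x$task, "): Da = ", round(x$da, 3), " over ",
      length(x$accuracies), " iterations", sep = "")
  if (!is.null(x$shuffled))
    cat("; shuffled control = ", round(mean(x$shuffled), 3), sep = "")
  cat("\n")
  invisible(x)
}

#' Rank neurons by single-neuron decoder accuracy
#'
#' Runs the single-region decoding procedure with X restricted to one
#' neuron at a time and orders neurons by their Da, descending; ties are
#' broken by neuron id (ascending).
#'
#' @param data a `labeled_dataset`.
#' @param repeats,folds,... passed to [decode_single_region()].
#' @param seed integer seed.
#' @return data.frame with `neuron` (column index), `neuron_id`, `da`,
#'   ordered best first.
#' @export
rank_best_neurons <- function(data, repeats = 5, folds = 5, seed = 1, ...) {
  stopifnot(inherits(data, "labeled_dataset"))
  da <- vapply(seq_len(ncol(data$X)), function(j) {
    dj <- data
    dj$X <- data$X[, j, drop = FALSE]
    decode_single_region(dj, n_neurons = 1, repeats = repeats,
                         folds = folds, seed = derive_seed(seed, j),
                         ...)$da
  }, numeric(1))
  ids <- if (!is.null(data$neuron_id)) data$neuron_id else
    seq_len(ncol(data$X))
  out <- data.frame(neuron = seq_len(ncol(data$X)), neuron_id = ids,
                    da = da)
  out <- out[order(-out$da, out$neuron_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-stimulus decoder transfer
#'
#' Trains a decoder on one stimulus dataset and applies it to another
#' (e.g. lick on R-CS, shock on F-CS, R-CS on F-CS, F-CS on R-CS).
#' Balancing and z-scoring parameters are fit on the training set only and
#' applied unchanged to the test set; the test set is under-sampled to
#' balanced classes so chance is 1/classes. A shuffled-test-label control
#' is evaluated alongside.
#'
#' @param train,test `labeled_dataset`s sharing the neuron set.
#' @param repeats training repetitions (default 10).
#' @param classifier,hidden,maxit,decay as in [decode_single_region()].
#' @param seed integer seed.
#' @return object of class `transfer_result`: list with `mean`,
#'   `accuracies` (per repeat), `shuffled` (control accuracies),
#'   `train_task`, `test_task`.
#' @export
cross_stimulus_transfer <- function(train, test, repeats = 10,
                                    classifier = "mlp", hidden = 16,
                                    maxit = 150, decay = 0.1, seed = 1) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(test, "labeled_dataset"))
  if (ncol(train$X) != ncol(test$X))
    stop("train and test must share the neuron/feature dimension")
  set.seed(seed)
  acc <- numeric(repeats)
  acc_sh <- numeric(repeats)
  for (r in seq_len(repeats)) {
    btr <- balance_undersample(train)
    bte <- balance_undersample(test)
    mu <- colMeans(btr$X)
    sdv <- apply(btr$X, 2, stats::sd)
    Xtr <- zscore_cols(btr$X, mu, sdv)
    Xte <- zscore_cols(bte$X, mu, sdv)
    pred <- fit_predict(Xtr, btr$y, Xte, classifier, hidden = hidden,
                        maxit = maxit, decay = decay)
    acc[r] <- mean(pred == bte$y)
    acc_sh[r] <- mean(pred == sample(bte$y))
  }
  structure(list(mean = mean(acc), accuracies = acc, shuffled = acc_sh,
                 train_task = train$task, test_task = test$task),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("Cross-stimulus transfer: accuracy = ", round(x$mean, 3),
      " (shuffled control ", round(mean(x$shuffled), 3), ") over ",
      length(x$accuracies), " repeats\n", sep = "")
  invisible(x)
}

#' Three-class CS discrimination
#'
#' Runs the single-region pipeline on a three-class dataset (class 0 =
#' pre-CS bins, 1 = R-CS bins, 2 = F-CS bins) and reports (1) the overall
#' three-class accuracy and (2) the conditional CS accuracy: among bins
#' whose true class is a CS class and whose prediction is also a CS class,
#' the fraction assigned to the correct CS.
#'
#' @param data a `labeled_dataset` with task "CS3".
#' @param n_neurons,repeats,folds,classifier,hidden,maxit,decay,seed as in
#'   [decode_single_region()].
#' @return object of class `discrimination_result`: list with `overall`,
#'   `conditional` (NA with `conditional_defined = FALSE` when no CS bin
#'   was predicted as CS), and per-iteration vectors.
#' @export
discriminate_cs <- function(data, n_neurons = NULL, repeats = 40,
                            folds = 5, classifier = "mlp", hidden = 16,
                            maxit = 150, decay = 0.1, seed = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (length(unique(data$y)) < 3)
    stop("three classes required for CS discrimination")
  if (is.null(n_neurons)) n_neurons <- ncol(data$X)
  set.seed(seed)
  overall <- numeric(repeats)
  conditional <- rep(NA_real_, repeats)
  for (r in seq_len(repeats)) {
    cols <- sort(sample.int(ncol(data$X), n_neurons))
    bal <- balance_undersample(data)
    X <- bal$X[, cols, drop = FALSE]
    y <- bal$y
    fold_id <- stratified_folds(y, folds)
    pred <- integer(length(y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      pred[!tr] <- fit_predict(zscore_cols(X[tr, , drop = FALSE], mu, sdv),
                               y[tr],
                               zscore_cols(X[!tr, , drop = FALSE], mu, sdv),
                               classifier, hidden = hidden, maxit = maxit,
                               decay = decay)
    }
    overall[r] <- mean(pred == y)
    cs_true <- y %in% c(1L, 2L)
    cs_pred_as_cs <- cs_true & pred %in% c(1L, 2L)
    if (any(cs_pred_as_cs))
      conditional[r] <- sum(pred == y & cs_pred_as_cs) / sum(cs_pred_as_cs)
  }
  structure(list(overall = mean(overall),
                 conditional = mean(conditional, na.rm = TRUE),
                 conditional_defined = any(!is.na(conditional)),
                 overall_iter = overall, conditional_iter = conditional),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("CS discrimination: overall = ", round(x$overall, 3),
      "; conditional CS accuracy = ",
      if (x$conditional_defined) round(x$conditional, 3) else "undefined",
      "\n", sep = "")
  invisible(x)
}

#' Multi-region random-forest decoding with feature importance
#'
#' Per iteration: draw `n_total` neurons with per-region counts
#' proportional to the pool composition (largest-remainder rounding),
#' balance classes by under-sampling, z-score, run stratified k-fold CV
#' with a random forest, and record the impurity-based feature importances
#' (normalized to sum to 1 over the drawn neurons) of a forest fit on the
#' full balanced iteration data. Reports the mean accuracy and per-region
#' mean importances over iterations.
#'
#' @param data a `labeled_dataset` whose columns carry region labels.
#' @param n_total neurons drawn per iteration (default 100).
#' @param repeats iterations (default 40).
#' @param folds CV folds (default 5).
#' @param num_trees forest size (default 100).
#' @param seed integer seed.
#' @return list with `result` (a `decoding_result`) and `importance` (an
#'   `importance_profile`: per-region iteration matrix `iters`, per-region
#'   means `region_mean`, per-neuron mean importances).
#' @export
decode_multi_region <- function(data, n_total = 100, repeats = 40,
                                folds = 5, num_trees = 100, seed = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  regions <- unique(data$regions)
  pool <- table(factor(data$regions, levels = regions))
  if (sum(pool) < n_total)
    n_total <- sum(pool)
  set.seed(seed)
  alloc <- largest_remainder(as.numeric(pool), n_total)
  acc <- numeric(repeats)
  imp_iter <- matrix(0, nrow = repeats, ncol = length(regions),
                     dimnames = list(NULL, regions))
  imp_neuron <- numeric(ncol(data$X))
  n_used <- numeric(ncol(data$X))
  for (r in seq_len(repeats)) {
    cols <- unlist(lapply(seq_along(regions), function(i) {
      idx <- which(data$regions == regions[i])
      sort(idx[sample.int(length(idx), alloc[i])])
    }))
    bal <- balance_undersample(data)
    X <- bal$X[, cols, drop = FALSE]
    y <- bal$y
    acc[r] <- cv_accuracy(X, y, folds, classifier = "rf",
                          num_trees = num_trees)
    # importance from a forest on the full balanced iteration data
    df <- data.frame(zscore_cols(X))
    df$.y <- factor(y)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = num_trees, importance = "impurity",
                          seed = sample.int(.Machine$integer.max, 1))
    imp <- fit$variable.importance
    imp <- imp / sum(imp)   # tree-impurity convention: sums to 1
    reg_cols <- data$regions[cols]
    imp_iter[r, ] <- vapply(regions, function(rr)
      mean(imp[reg_cols == rr]), numeric(1))
    imp_neuron[cols] <- imp_neuron[cols] + imp
    n_used[cols] <- n_used[cols] + 1
  }
  profile <- structure(list(regions = regions,
                            iters = imp_iter,
                            region_mean = colMeans(imp_iter),
                            neuron_mean = ifelse(n_used > 0,
                                                 imp_neuron / pmax(n_used, 1),
                                                 NA_real_),
                            n_iter = repeats),
                       class = "importance_profile")
  res <- structure(list(da = mean(acc), accuracies = acc, shuffled = NULL,
                        task = data$task,
                        spec = list(n_total = n_total, repeats = repeats,
                                    folds = folds, classifier = "rf",
                                    seed = seed)),
                   class = "decoding_result")
  list(result = res, importance = profile)
}

#' @export
print.importance_profile <- function(x, ...) {
  cat("Feature-importance profile over", x$n_iter, "iterations:\n")
  print(round(x$region_mean, 4))
  invisible(x)
}

#' Contrast two feature-importance profiles
#'
#' Per region: difference of mean importances (a - b) and a two-sided
#' permutation p-value obtained by pooling the per-iteration values of the
#' two profiles and permuting group membership.
#'
#' @param a,b `importance_profile`s over the same region set with the same
#'   iteration count.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame with `region`, `difference`, `p_value`.
#' @export
contrast_importance <- function(a, b, n_perm = 10000, seed = 1) {
  stopifnot(inherits(a, "importance_profile"),
            inherits(b, "importance_profile"))
  if (!identical(sort(a$regions), sort(b$regions)))
    stop("importance profiles cover different region sets")
  if (a$n_iter != b$n_iter)
    stop("importance profiles have different iteration counts")
  set.seed(seed)
  out <- data.frame(region = a$regions, difference = NA_real_,
                    p_value = NA_real_)
  for (i in seq_along(a$regions)) {
    va <- a$iters[, a$regions[i]]
    vb <- b$iters[, a$regions[i]]
    obs <- mean(va) - mean(vb)
    pool <- c(va, vb)
    na <- length(va)
    cnt <- 0L
    for (p in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      d <- mean(pool[idx]) - mean(pool[-idx])
      if (abs(d) >= abs(obs) - 1e-15) cnt <- cnt + 1L
    }
    out$difference[i] <- obs
    out$p_value[i] <- (cnt + 1) / (n_perm + 1)
  }
  out
}
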