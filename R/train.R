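#' Train the reference feature-based classifier
#'
#' A multinomial logistic model over handcrafted morphology features
#' (see [patch_features()]), trained by full-batch gradient descent on
#' a class-weighted cross-entropy loss with L2 weight decay. The
#' training loop is driven by the schedule state machines: the
#' learning rate follows [plateau_step()] on the validation loss and
#' training halts via [early_stop_step()], restoring the weights of the
#' best validation epoch. This realizes the published training
#' protocol (weighted loss, LR-on-plateau, early stopping, fold
#' ensembling) at desk scale; deep backbones remain pluggable behind
#' the same classifier contract.
#'
#' @param x Numeric feature matrix (rows = samples), or a list of
#'   pixel patches from which [patch_features()] are computed.
#' @param labels Class label per row; at least two distinct classes.
#' @param weights Optional named per-class loss weights (e.g. from
#'   [class_weights()]); default uniform.
#' @param schedule A [train_schedule()]. The default learning rate
#'   here is 0.5: full-batch descent on standardized low-dimensional
#'   features supports far larger steps than the minibatch deep-net
#'   setting the schedule's 1e-4 default is meant for.
#' @param val_fraction Fraction held out (stratified) for the
#'   validation signal driving the schedules; classes too small to
#'   stratify fall back to validating on the training set
#'   (default 0.2).
#' @param seed Integer seed (initialization and the validation split).
#' @return Object of class `rbc_classifier` with `coef` (K x (p+1)),
#'   `classes`, feature `centers`/`scales`, and a training `history`
#'   (per-epoch loss, validation loss, learning rate, best epoch).
#' @export
train_reference_classifier <- function(x, labels, weights = NULL,
                                       schedule = train_schedule(
                                         initial_lr = 0.5),
                                       val_fraction = 0.2, seed = 1L) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, patch_features))
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training requires at least two classes")
  y <- match(labels, classes)
  K <- length(classes)
  n <- nrow(x)

  centers <- colMeans(x)
  scales <- apply(x, 2, sd)
  scales[scales < 1e-8] <- 1
  xs <- sweep(sweep(x, 2, centers), 2, scales, "/")
  X <- cbind(1, xs)
  p1 <- ncol(X)

  w_class <- rep(1, K)
  if (!is.null(weights)) {
    if (is.null(names(weights))) {
      if (length(weights) != K) stop("unnamed weights must have one per class")
      w_class <- as.numeric(weights)
    } else {
      miss <- setdiff(classes, names(weights))
      if (length(miss)) stop("missing weights for: ",
                             paste(miss, collapse = ", "))
      w_class <- as.numeric(weights[classes])
    }
  }
  w_i <- w_class[y]

  # stratified validation split where feasible
  kval <- max(2L, round(1 / val_fraction))
  counts <- table(labels)
  if (all(counts >= kval)) {
    fold <- stratified_folds(labels, k = kval, seed = seed)
    val <- fold == 1L
  } else {
    val <- rep(FALSE, n)
  }
  tr <- if (any(val)) !val else rep(TRUE, n)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y)] <- 1

  softmax <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    E / rowSums(E)
  }
  wce <- function(P, rows) {
    -sum(w_i[rows] * log(pmax(P[cbind(seq_along(rows), y[rows])], 1e-12))) /
      sum(w_i[rows])
  }

  W <- local_seed(seed, matrix(rnorm(p1 * K, sd = 0.01), p1, K))
  es <- early_stop_state(schedule$early_patience, schedule$early_min_delta,
                         mode = "min")
  pl <- plateau_state(schedule$initial_lr, schedule$plateau_patience,
                      schedule$plateau_factor, schedule$min_lr)
  best_W <- W
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  rows_tr <- which(tr)
  rows_val <- which(if (any(val)) val else tr)
  n_tr <- length(rows_tr)
  for (epoch in seq_len(schedule$max_epochs)) {
    P <- softmax(X[rows_tr, , drop = FALSE] %*% W)
    G <- t(X[rows_tr, , drop = FALSE]) %*%
      ((P - Y[rows_tr, , drop = FALSE]) * w_i[rows_tr]) /
      sum(w_i[rows_tr]) + schedule$weight_decay * W
    W <- W - pl$lr * G
    train_loss <- wce(softmax(X[rows_tr, , drop = FALSE] %*% W), rows_tr)
    val_loss <- wce(softmax(X[rows_val, , drop = FALSE] %*% W), rows_val)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss, lr = pl$lr))
    pl <- plateau_step(pl, val_loss)
    es <- early_stop_step(es, val_loss)
    if (es$best_index == epoch) best_W <- W
    if (es$stop) break
  }
  structure(
    list(coef = best_W, classes = classes, centers = centers,
         scales = scales, history = history,
         best_epoch = es$best_index, n_train = n_tr,
         weights = setNames(w_class, classes)),
    class = "rbc_classifier"
  )
}

#' @export
print.rbc_classifier <- function(x, ...) {
  cat(sprintf(
    "<rbc_classifier> %d classes (%s), %d features, best epoch %d/%d\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    nrow(x$coef) - 1L, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' Predict class probabilities from the reference classifier
#'
#' @param object An `rbc_classifier`.
#' @param newdata Feature matrix (rows = samples), a single feature
#'   vector, or a list of pixel patches.
#' @param type `"prob"` (default) for the probability matrix or
#'   `"class"` for argmax labels.
#' @param ... Unused.
#' @return Probability matrix (samples x classes) or label vector.
#' @export
predict.rbc_classifier <- function(object, newdata, type = c("prob", "class"),
                                   ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.data.frame(newdata)) {
    newdata <- do.call(rbind, lapply(newdata, patch_features))
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  xs <- sweep(sweep(as.matrix(newdata), 2, object$centers), 2,
              object$scales, "/")
  Z <- cbind(1, xs) %*% object$coef
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z) / rowSums(exp(Z))
  colnames(P) <- object$classes
  if (type == "class") return(object$classes[apply(P, 1, which.max)])
  P
}

#' Wrap a trained classifier as a pipeline fold model
#'
#' @param model An `rbc_classifier`.
#' @return Function `patch matrix -> named probability vector`,
#'   meeting the classifier contract of [run_two_step()].
#' @export
as_classifier_fun <- function(model) {
  function(patch) {
    f <- patch_features(patch)
    drop(predict(model, matrix(f, nrow = 1)))
  }
}

#' Train one classifier per fold
#'
#' Stratified k-fold split, per-fold class weights computed from each
#' fold's own training distribution (the within-fold weighting of the
#' protocol), one [train_reference_classifier()] per fold.
#'
#' @param x Feature matrix or list of patches.
#' @param labels Class labels.
#' @param k Number of folds (default 5).
#' @param scheme Class-weight scheme (default `"inverse"`).
#' @param schedule A [train_schedule()].
#' @param seed Integer seed.
#' @return List of `k` `rbc_classifier`s with fold assignment as
#'   attribute `folds`.
#' @export
train_fold_models <- function(x, labels, k = 5, scheme = "inverse",
                              schedule = train_schedule(initial_lr = 0.5),
                              seed = 1L) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, patch_features))
  }
  folds <- stratified_folds(labels, k = k, seed = seed)
  seeds <- derive_seeds(seed, k)
  models <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    counts <- table(labels[tr])
    w <- class_weights(as.numeric(counts), scheme = scheme)
    names(w) <- names(counts)
    train_reference_classifier(x[tr, , drop = FALSE], labels[tr],
                               weights = w, schedule = schedule,
                               seed = seeds[f])
  })
  attr(models, "folds") <- folds
  models
}
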