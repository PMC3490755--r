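# Classifiers: Naive Bayes with Laplace estimation for binary features and
# per-class Gaussians for continuous features, and soft-margin SVM with
# polynomial or RBF kernel (quadratic program delegated to libsvm via e1071;
# the stored model is evaluated through its own dual expansion).

#' Kernel specification
#'
#' Polynomial kernel K(xi, xj) = (xi . xj + 1)^p and radial basis function
#' kernel K(xi, xj) = exp(-gamma ||xi - xj||^2).
#'
#' @param family \code{"polynomial"} or \code{"rbf"}.
#' @param p Polynomial degree (default 1, i.e. the linear kernel).
#' @param gamma RBF width (default 0.01).
#' @return A \code{kernel_spec} list.
#' @export
kernel_spec <- function(family = c("polynomial", "rbf"), p = 1, gamma = 0.01) {
  family <- match.arg(family)
  stopifnot(p >= 1, p == as.integer(p), gamma > 0)
  structure(list(family = family, p = as.integer(p), gamma = gamma),
            class = "kernel_spec")
}

#' Evaluate a kernel between two vectors
#'
#' @param spec A [kernel_spec()].
#' @param xi,xj Numeric vectors of equal length.
#' @return Scalar kernel value.
#' @export
kernel_eval <- function(spec, xi, xj) {
  if (length(xi) != length(xj)) stop("kernel_eval: dimension mismatch")
  if (spec$family == "polynomial") {
    (sum(xi * xj) + 1)^spec$p
  } else {
    exp(-spec$gamma * sum((xi - xj)^2))
  }
}

# kernel matrix between rows of a and rows of b
kernel_matrix <- function(spec, a, b) {
  if (spec$family == "polynomial") {
    (tcrossprod(a, b) + 1)^spec$p
  } else {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    exp(-spec$gamma * pmax(d2, 0))
  }
}

#' Training configuration
#'
#' Defaults follow the study conventions: no parameter tuning, polynomial
#' degree p = 1, RBF gamma = 0.01, penalty C = 1.0, and class balancing by
#' undersampling for SVM training.
#'
#' @param algorithm \code{"nb"} or \code{"svm"}.
#' @param kernel A [kernel_spec()] (SVM only).
#' @param C Soft-margin penalty (default 1.0).
#' @param balance Undersample the majority class before training (default
#'   \code{TRUE} for SVM, \code{FALSE} for NB).
#' @param seed Seed feeding the undersampler.
#' @return A \code{train_config} list.
#' @export
train_config <- function(algorithm = c("svm", "nb"), kernel = kernel_spec(),
                         C = 1.0, balance = (algorithm == "svm"), seed = 1) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, kernel = kernel, C = C,
                 balance = isTRUE(balance), seed = as.integer(seed)),
            class = "train_config")
}

# ---- Naive Bayes ------------------------------------------------------------

NB_VAR_FLOOR <- 1e-9

#' Train a Naive Bayes classifier
#'
#' Class priors are the training class frequencies. Binary (0/1) features get
#' add-one Laplace-smoothed conditional probabilities per class,
#' (k + 1) / (n_c + 2); continuous features get per-class Gaussians with a
#' variance floor of 1e-9.
#'
#' @param features A \code{rip_features} (both classes must be present).
#' @return An \code{rip_nb} model.
#' @export
train_nb <- function(features) {
  stopifnot(inherits(features, "rip_features"))
  x <- features$x
  y <- features$meta$label
  if (length(unique(y)) < 2) stop("train_nb: both classes must be present")

  is_binary <- apply(x, 2, function(col) all(col %in% c(0, 1)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)

  bin <- NULL
  if (any(is_binary)) {
    xb <- x[, is_binary, drop = FALSE]
    bin <- list(
      cols = which(is_binary),
      # P(X_i = 1 | C = c), Laplace add-one over the two values
      p1_c1 = (colSums(xb[y == 1L, , drop = FALSE]) + 1) / (n1 + 2),
      p1_c0 = (colSums(xb[y == 0L, , drop = FALSE]) + 1) / (n0 + 2)
    )
  }
  gauss <- NULL
  if (any(!is_binary)) {
    xg <- x[, !is_binary, drop = FALSE]
    colvar <- function(m) {
      if (nrow(m) < 2) return(rep(NB_VAR_FLOOR, ncol(m)))
      apply(m, 2, stats::var)
    }
    gauss <- list(
      cols = which(!is_binary),
      mean_c1 = colMeans(xg[y == 1L, , drop = FALSE]),
      mean_c0 = colMeans(xg[y == 0L, , drop = FALSE]),
      var_c1 = pmax(colvar(xg[y == 1L, , drop = FALSE]), NB_VAR_FLOOR),
      var_c0 = pmax(colvar(xg[y == 0L, , drop = FALSE]), NB_VAR_FLOOR)
    )
  }
  structure(
    list(prior_c1 = n1 / (n1 + n0), prior_c0 = n0 / (n1 + n0),
         binary = bin, gaussian = gauss, n_features = ncol(x),
         n_train = length(y)),
    class = "rip_nb"
  )
}

#' Naive Bayes ranking score
#'
#' The log posterior ratio log P(C=1|x) - log P(C=0|x), computed in log
#' space. The predicted label is 1 when the score is >= 0 (posterior ratio
#' >= 1, ties to the interface class).
#'
#' @param model An \code{rip_nb}.
#' @param x Numeric feature vector, or a matrix with one instance per row.
#' @return Numeric score(s).
#' @export
nb_score <- function(model, x) {
  stopifnot(inherits(model, "rip_nb"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features) {
    stop("nb_score: expected ", model$n_features, " features, got ", ncol(x))
  }
  s <- rep(log(model$prior_c1) - log(model$prior_c0), nrow(x))
  if (!is.null(model$binary)) {
    xb <- x[, model$binary$cols, drop = FALSE]
    w1 <- log(model$binary$p1_c1) - log(model$binary$p1_c0)
    w0 <- log1p(-model$binary$p1_c1) - log1p(-model$binary$p1_c0)
    s <- s + drop(xb %*% w1) + drop((1 - xb) %*% w0)
  }
  if (!is.null(model$gaussian)) {
    g <- model$gaussian
    xg <- x[, g$cols, drop = FALSE]
    ll1 <- -0.5 * (sweep(xg, 2, g$mean_c1)^2 %*% (1 / g$var_c1)) -
      0.5 * sum(log(2 * pi * g$var_c1))
    ll0 <- -0.5 * (sweep(xg, 2, g$mean_c0)^2 %*% (1 / g$var_c0)) -
      0.5 * sum(log(2 * pi * g$var_c0))
    s <- s + drop(ll1) - drop(ll0)
  }
  s
}

# ---- SVM --------------------------------------------------------------------

#' Train a soft-margin SVM
#'
#' Solves the standard soft-margin dual (the quadratic program is delegated
#' to libsvm through \pkg{e1071}); the returned model stores the support
#' vectors, dual coefficients (alpha_i y_i), bias and kernel, and
#' [svm_score()] evaluates the dual expansion f(x) = sum_i coef_i K(x_i, x) +
#' b directly. Training instances should already be class-balanced when
#' balancing is wanted (see [undersample()] and [train_classifier()]).
#'
#' @param features A \code{rip_features}.
#' @param kernel A [kernel_spec()].
#' @param C Soft-margin penalty (default 1.0).
#' @return An \code{rip_svm} model.
#' @export
train_svm <- function(features, kernel = kernel_spec(), C = 1.0) {
  stopifnot(inherits(features, "rip_features"),
            inherits(kernel, "kernel_spec"))
  x <- features$x
  y <- features$meta$label
  if (length(unique(y)) < 2) stop("train_svm: both classes must be present")
  yf <- factor(y, levels = c("1", "0"))  # class "1" gets positive decisions

  fit <- if (kernel$family == "polynomial") {
    e1071::svm(x, yf, scale = FALSE, kernel = "polynomial",
               degree = kernel$p, gamma = 1, coef0 = 1, cost = C)
  } else {
    e1071::svm(x, yf, scale = FALSE, kernel = "radial",
               gamma = kernel$gamma, cost = C)
  }
  # libsvm orients the decision function toward the class first seen in the
  # training data; normalise so class "1" always gets positive values
  sgn <- if (levels(yf)[fit$labels[1]] == "1") 1 else -1
  structure(
    list(support_vectors = unname(as.matrix(fit$SV)),
         dual_coefs = sgn * drop(fit$coefs), bias = -sgn * fit$rho,
         kernel = kernel, C = C, n_features = ncol(x),
         n_train = length(y)),
    class = "rip_svm"
  )
}

#' SVM decision value
#'
#' Signed distance-like decision value f(x); the predicted label is 1 when
#' f(x) >= 0.
#'
#' @param model An \code{rip_svm}.
#' @param x Feature vector or matrix of instances (rows).
#' @return Numeric score(s).
#' @export
svm_score <- function(model, x) {
  stopifnot(inherits(model, "rip_svm"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features) {
    stop("svm_score: expected ", model$n_features, " features, got ", ncol(x))
  }
  K <- kernel_matrix(model$kernel, model$support_vectors, x)
  drop(crossprod(K, model$dual_coefs)) + model$bias
}

# ---- Common surface ---------------------------------------------------------

#' Train a classifier under a configuration
#'
#' Applies undersampling when the configuration asks for it (seeded), then
#' trains the requested classifier.
#'
#' @param features A \code{rip_features}.
#' @param config A [train_config()].
#' @return An \code{rip_nb} or \code{rip_svm}, with the resolved config
#'   attached as attribute \code{"config"}.
#' @export
train_classifier <- function(features, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (config$balance) features <- undersample(features, config$seed)
  model <- if (config$algorithm == "nb") {
    train_nb(features)
  } else {
    train_svm(features, kernel = config$kernel, C = config$C)
  }
  attr(model, "config") <- config
  model
}

score_instances <- function(model, x) {
  if (inherits(model, "rip_nb")) nb_score(model, x) else svm_score(model, x)
}

#' Predict interface residues
#'
#' @param object A trained \code{rip_nb} or \code{rip_svm}.
#' @param features A \code{rip_features} to score.
#' @param threshold Decision threshold on the ranking score (default 0,
#'   which reproduces the classifiers' native decision rules; label 1 when
#'   score >= threshold).
#' @param ... Unused.
#' @return A prediction tibble: \code{chain_id}, \code{position},
#'   \code{residue}, \code{score}, \code{pred}, \code{label}.
#' @export
predict.rip_nb <- function(object, features, threshold = 0, ...) {
  predict_features(object, features, threshold)
}

#' @rdname predict.rip_nb
#' @export
predict.rip_svm <- function(object, features, threshold = 0, ...) {
  predict_features(object, features, threshold)
}

predict_features <- function(model, features, threshold = 0) {
  stopifnot(inherits(features, "rip_features"))
  s <- score_instances(model, features$x)
  tibble::tibble(
    chain_id = features$meta$chain_key,
    position = features$meta$position,
    residue = features$meta$residue,
    score = s,
    pred = as.integer(s >= threshold),
    label = features$meta$label
  )
}

#' @export
print.rip_nb <- function(x, ...) {
  cat("<rip_nb> Naive Bayes: ", x$n_features, " features (",
      if (is.null(x$binary)) 0 else length(x$binary$cols), " binary, ",
      if (is.null(x$gaussian)) 0 else length(x$gaussian$cols),
      " Gaussian), trained on ", x$n_train, " instances\n", sep = "")
  invisible(x)
}

#' @export
print.rip_svm <- function(x, ...) {
  cat("<rip_svm> ", x$kernel$family, " kernel",
      if (x$kernel$family == "polynomial") paste0(" (p=", x$kernel$p, ")")
      else paste0(" (gamma=", x$kernel$gamma, ")"),
      ", C=", x$C, ", ", nrow(x$support_vectors), " support vectors\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Naive Bayes model
#'
#' One row per (feature, statistic): Laplace-smoothed P(X=1|C) for binary
#' features, class-conditional mean and variance for Gaussian features.
#'
#' @param x An \code{rip_nb}.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rip_nb <- function(x, ...) {
  out <- list()
  if (!is.null(x$binary)) {
    out$bin <- tibble::tibble(
      feature = x$binary$cols, kind = "binary",
      statistic = "p_x1", class1 = unname(x$binary$p1_c1),
      class0 = unname(x$binary$p1_c0)
    )
  }
  if (!is.null(x$gaussian)) {
    g <- x$gaussian
    out$gm <- tibble::tibble(feature = g$cols, kind = "gaussian",
                             statistic = "mean",
                             class1 = unname(g$mean_c1),
                             class0 = unname(g$mean_c0))
    out$gv <- tibble::tibble(feature = g$cols, kind = "gaussian",
                             statistic = "variance",
                             class1 = unname(g$var_c1),
                             class0 = unname(g$var_c0))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$feature, .data$statistic)
}

#' @rdname tidy.rip_nb
#' @export
glance.rip_nb <- function(x, ...) {
  tibble::tibble(algorithm = "nb", n_features = x$n_features,
                 n_train = x$n_train, prior_interface = x$prior_c1)
}

#' Tidy an SVM model
#'
#' One row per support vector with its dual coefficient alpha_i y_i.
#'
#' @param x An \code{rip_svm}.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rip_svm <- function(x, ...) {
  tibble::tibble(support_vector = seq_along(x$dual_coefs),
                 dual_coef = x$dual_coefs)
}

#' @rdname tidy.rip_svm
#' @export
glance.rip_svm <- function(x, ...) {
  tibble::tibble(algorithm = "svm", kernel = x$kernel$family,
                 p = x$kernel$p, gamma = x$kernel$gamma, C = x$C,
                 n_support = nrow(x$support_vectors),
                 n_features = x$n_features, n_train = x$n_train,
                 bias = x$bias)
}

# ---- Serialization ----------------------------------------------------------

#' Serialize / restore a trained model as JSON
#'
#' Versioned JSON envelope carrying priors and conditional tables for NB, or
#' support vectors, dual coefficients, kernel and C for SVM.
#'
#' @param model An \code{rip_nb} or \code{rip_svm}.
#' @param path Output path.
#' @return \code{write_model} returns \code{path} invisibly; \code{read_model}
#'   the restored model.
#' @export
write_model <- function(model, path) {
  env <- list(format = "rnaiface-model", version = 1L)
  if (inherits(model, "rip_nb")) {
    env$algorithm <- "nb"
    env$model <- unclass(model)
  } else if (inherits(model, "rip_svm")) {
    env$algorithm <- "svm"
    env$model <- list(support_vectors = model$support_vectors,
                      dual_coefs = model$dual_coefs, bias = model$bias,
                      kernel = unclass(model$kernel), C = model$C,
                      n_features = model$n_features, n_train = model$n_train)
  } else {
    stop("unsupported model class")
  }
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  env <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(env$format, "rnaiface-model")) {
    stop("not an rnaiface model file: ", path)
  }
  m <- env$model
  if (env$algorithm == "nb") {
    if (!is.null(m$binary)) m$binary$cols <- as.integer(m$binary$cols)
    if (!is.null(m$gaussian)) m$gaussian$cols <- as.integer(m$gaussian$cols)
    structure(m, class = "rip_nb")
  } else {
    structure(
      list(support_vectors = as.matrix(m$support_vectors),
           dual_coefs = as.numeric(m$dual_coefs), bias = m$bias,
           kernel = structure(m$kernel, class = "kernel_spec"), C = m$C,
           n_features = m$n_features, n_train = m$n_train),
      class = "rip_svm"
    )
  }
}
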