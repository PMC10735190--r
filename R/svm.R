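#' @title Polynomial-kernel support vector machine
#' @name svm
#' @description
#' Soft-margin SVM on standardized predictors with the polynomial kernel
#' `K(x, z) = (x . z / gamma + 1)^order`, `gamma` being the number of
#' retained features — the usual "standardize + polynomial" semantics. The
#' dual quadratic program is solved exactly with `quadprog`, so training is
#' deterministic. `class_1` codes the rest state (y = -1) and `class_2` the
#' task state (y = +1); a decision value of exactly zero is resolved to
#' `class_1`, conservative toward the null (rest) state.
NULL

.svm_kernel <- function(A, B, gamma, order) (tcrossprod(A, B) / gamma + 1)^order

#' Train a polynomial-kernel SVM
#'
#' Features are standardized with training-set location/scale only;
#' zero-variance training features are excluded from the model and ignored
#' at prediction time.
#'
#' @param x Numeric matrix, one row per training vector.
#' @param y Labels, values `"class_1"` / `"class_2"` (character or factor).
#' @param order Polynomial kernel order (default 4).
#' @param C Soft-margin box constraint (default 1).
#' @return Object of class `cogload_svm`.
#' @export
train_svm <- function(x, y, order = 4L, C = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (!all(y %in% c("class_1", "class_2")))
    stop("labels must be class_1 or class_2", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("invalid training set: both classes required", call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y size mismatch", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  keep <- which(scl > 0)
  if (length(keep) == 0L) stop("all features are constant", call. = FALSE)
  xs <- scale(x[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  yy <- ifelse(y == "class_2", 1, -1)
  n <- nrow(xs)
  gamma <- length(keep)
  K <- .svm_kernel(xs, xs, gamma, order)
  D <- (yy %o% yy) * K
  D <- D + diag(1e-8 * max(diag(D)), n)        # PD ridge for the QP solver
  A <- cbind(yy, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- which(alpha > 1e-8)
  f0 <- as.vector(K[, sv, drop = FALSE] %*% (alpha[sv] * yy[sv]))
  margin <- sv[alpha[sv] < C - 1e-6]
  if (length(margin) == 0L) margin <- sv
  b <- mean(yy[margin] - f0[margin])
  structure(list(order = order, C = C, gamma = gamma,
                 center = ctr, scale = scl, keep = keep,
                 sv_x = xs[sv, , drop = FALSE],
                 sv_coef = alpha[sv] * yy[sv], b = b,
                 p = ncol(x)),
            class = "cogload_svm")
}

#' Decision values of an SVM model
#'
#' @param model A `cogload_svm`.
#' @param newdata Numeric matrix with the training dimensionality.
#' @return Numeric vector of decision-function values (positive means
#'   `class_2`).
#' @export
decision_values <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != model$p)
    stop("dimensionality mismatch: model expects ", model$p, " features",
         call. = FALSE)
  xs <- scale(newdata[, model$keep, drop = FALSE],
              center = model$center[model$keep],
              scale = model$scale[model$keep])
  K <- .svm_kernel(xs, model$sv_x, model$gamma, model$order)
  as.vector(K %*% model$sv_coef) + model$b
}

#' Predict class labels
#'
#' @param object A `cogload_svm`.
#' @param newdata Numeric matrix of feature vectors.
#' @param ... Unused.
#' @return Character vector of `"class_1"` / `"class_2"` labels; exact-zero
#'   decision values resolve to `"class_1"`.
#' @export
predict.cogload_svm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata)
  ifelse(f > 0, "class_2", "class_1")
}

#' @export
print.cogload_svm <- function(x, ...) {
  cat("<cogload_svm> polynomial order ", x$order, ", C = ", x$C, ", ",
      nrow(x$sv_x), " support vectors, ", length(x$keep), "/", x$p,
      " features retained\n", sep = "")
  invisible(x)
}
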