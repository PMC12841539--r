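#' SVM configuration
#'
#' Settings for the damage classifier. Kernels follow the standard forms:
#' linear `K(x1,x2) = x1.x2`; RBF `K(x1,x2) = exp(-gamma ||x1-x2||^2)`
#' (default `gamma = 0.1`); polynomial `K(x1,x2) = (gamma x1.x2 + r)^d`
#' (default degree 3). Feature standardization is on by default: the eight
#' descriptors span four orders of magnitude (area ~8000 px^2 versus
#' eccentricity ~0.5), so unstandardized RBF distances would be dominated by
#' area alone.
#'
#' @param kernel `"rbf"` (default), `"linear"` or `"polynomial"`.
#' @param gamma kernel scale for rbf/polynomial (default 0.1).
#' @param coef_r polynomial offset r (default 1, the inhomogeneous form whose expansion keeps all lower-order terms).
#' @param degree polynomial degree d (default 3).
#' @param C soft-margin penalty (default 1).
#' @param standardize standardize features using training-set statistics
#'   (default TRUE).
#' @return object of class `svm_config`.
#' @export
svm_config <- function(kernel = c("rbf", "linear", "polynomial"), gamma = 0.1,
                       coef_r = 1, degree = 3L, C = 1, standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (kernel != "linear" && gamma <= 0) stop("gamma must be positive")
  if (degree < 1 || degree != round(degree)) stop("degree must be a positive integer")
  if (C <= 0) stop("C must be positive")
  structure(
    list(
      kernel = kernel, gamma = gamma, coef_r = coef_r,
      degree = as.integer(degree), C = C, standardize = isTRUE(standardize)
    ),
    class = "svm_config"
  )
}

#' Evaluate an SVM kernel function
#'
#' @param x1,x2 equal-length numeric vectors.
#' @param config an [svm_config()].
#' @return scalar kernel value.
#' @export
kernel_value <- function(x1, x2, config = svm_config()) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  switch(config$kernel,
    linear = sum(x1 * x2),
    rbf = exp(-config$gamma * sum((x1 - x2)^2)),
    polynomial = (config$gamma * sum(x1 * x2) + config$coef_r)^config$degree
  )
}

#' Gram matrix of an SVM kernel
#'
#' @param x numeric matrix (rows are observations).
#' @param config an [svm_config()].
#' @return symmetric `nrow(x)` x `nrow(x)` kernel matrix.
#' @export
kernel_gram <- function(x, config = svm_config()) {
  g <- x %*% t(x)
  switch(config$kernel,
    linear = g,
    polynomial = (config$gamma * g + config$coef_r)^config$degree,
    rbf = {
      sq <- rowSums(x^2)
      d2 <- outer(sq, sq, "+") - 2 * g
      exp(-config$gamma * pmax(d2, 0))
    }
  )
}

#' Fit the kernel damage classifier
#'
#' Trains a soft-margin SVM on kernel records, with `damaged` as the positive
#' class. The max-margin optimisation is delegated to libsvm (via e1071); the
#' feature protocol, kernel parametrisation and class conventions live here.
#' Deterministic for fixed inputs.
#'
#' @param records data frame with the eight feature columns and a `label`
#'   column containing `"intact"` / `"damaged"` (see [extract_features()]).
#' @param config an [svm_config()].
#' @return object of class `kernel_svm`.
#' @export
svm_fit <- function(records, config = svm_config()) {
  labs <- factor(records$label, levels = c("intact", "damaged"))
  if (anyNA(labs)) stop("labels must be 'intact' or 'damaged'")
  if (length(unique(labs)) < 2L) {
    stop("training data must contain both classes")
  }
  x <- as.matrix(records[, feature_columns()])
  fit <- e1071::svm(
    x = x, y = labs,
    type = "C-classification",
    kernel = switch(config$kernel,
      linear = "linear", rbf = "radial", polynomial = "polynomial"
    ),
    gamma = if (config$kernel == "linear") 1 / ncol(x) else config$gamma,
    coef0 = config$coef_r,
    degree = config$degree,
    cost = config$C,
    scale = config$standardize
  )
  structure(list(config = config, fit = fit), class = "kernel_svm")
}

#' Predict intact/damaged labels
#'
#' @param model a [svm_fit()] model.
#' @param records data frame with the eight feature columns (order-preserving:
#'   one label per row).
#' @param decision also return the signed decision values (attribute
#'   `"decision"`); positive values side with `damaged`.
#' @return character vector of `"intact"` / `"damaged"`.
#' @export
svm_predict <- function(model, records, decision = FALSE) {
  if (nrow(records) == 0L) {
    out <- character(0)
    if (decision) attr(out, "decision") <- numeric(0)
    return(out)
  }
  x <- as.matrix(records[, feature_columns()])
  p <- predict(model$fit, x, decision.values = decision)
  out <- as.character(p)
  if (decision) {
    dv <- drop(attr(p, "decision.values"))
    # orient: positive = damaged
    if (grepl("^intact", colnames(attr(p, "decision.values"))[1])) dv <- -dv
    attr(out, "decision") <- unname(dv)
  }
  out
}
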