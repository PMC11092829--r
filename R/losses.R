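#' Inverse-frequency class weights
#'
#' Computes the balanced class weights \eqn{\alpha(c) = N / (K \cdot N_c)},
#' where `N` is the total sample count, `K` the number of classes and `N_c`
#' the count of class `c`. The weights satisfy \eqn{\sum_c N_c \alpha(c) = N}
#' by construction, which is asserted.
#'
#' @param class_counts Named vector of positive per-class counts.
#' @return An object of class `class_weight_spec` with fields `class_counts`,
#'   `n_total`, `n_classes` and `weights`.
#' @examples
#' # a severely imbalanced 5-grade clinical label
#' cw <- class_weights(c(g0 = 15210, g1 = 162, g2 = 310, g3 = 190, g4 = 394))
#' round(cw$weights, 4)
#' @export
class_weights <- function(class_counts) {
  if (is.null(names(class_counts)) || any(names(class_counts) == "")) {
    stop("'class_counts' must be a fully named vector", call. = FALSE)
  }
  bad <- names(class_counts)[class_counts <= 0]
  if (length(bad)) {
    stop(sprintf("class '%s' has a non-positive count; its weight is undefined",
                 bad[1L]), call. = FALSE)
  }
  n <- sum(class_counts)
  k <- length(class_counts)
  w <- n / (k * class_counts)
  stopifnot(abs(sum(class_counts * w) - n) < 1e-8 * n)
  structure(list(class_counts = class_counts, n_total = n, n_classes = k,
                 weights = w),
            class = "class_weight_spec")
}

#' @export
print.class_weight_spec <- function(x, ...) {
  cat(sprintf("<class_weight_spec> %d classes, N = %d\n", x$n_classes,
              as.integer(x$n_total)))
  print(round(x$weights, 4))
  invisible(x)
}

#' Class-weighted focal loss
#'
#' Mean over samples of
#' \deqn{-\alpha_{y}\,(1 - p_{y})^{\gamma}\,\log p_{y},}
#' where \eqn{p_y} is the predicted probability of the true class, `gamma`
#' the focusing parameter down-weighting easy examples, and \eqn{\alpha_y}
#' the class weight. With `gamma = 0` and unit weights this is the ordinary
#' cross-entropy. Probabilities are clamped at `1e-12` before the log.
#'
#' @param probs `N x K` matrix of predicted class probabilities (rows
#'   summing to 1); columns named by class.
#' @param labels Factor or character vector of true classes, matched against
#'   `colnames(probs)`.
#' @param gamma Non-negative focusing parameter (default 2).
#' @param weights Optional `class_weight_spec` or named numeric vector of
#'   class weights; defaults to unit weights.
#' @return Scalar loss.
#' @export
focal_loss <- function(probs, labels, gamma = 2, weights = NULL) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) {
    stop("'probs' must have class names as column names", call. = FALSE)
  }
  if (gamma < 0) stop("'gamma' must be >= 0", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(probs)) {
    stop("'labels' length must match rows of 'probs'", call. = FALSE)
  }
  unknown <- setdiff(unique(labels), colnames(probs))
  if (length(unknown)) {
    stop(sprintf("label '%s' is outside the declared class set", unknown[1L]),
         call. = FALSE)
  }
  if (inherits(weights, "class_weight_spec")) weights <- weights$weights
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, ncol(probs)), colnames(probs))
  }
  idx <- match(labels, colnames(probs))
  p_t <- pmax(probs[cbind(seq_along(idx), idx)], 1e-12)
  alpha <- unname(weights[colnames(probs)[idx]])
  mean(-alpha * (1 - p_t)^gamma * log(p_t))
}

#' L2-regularised loss (weight decay)
#'
#' \deqn{L_{reg} = L + \frac{\lambda}{2}\,\lVert\theta\rVert_2^2} over the
#' weight matrices of a model. Following the usual weight-decay convention
#' only weights are penalised; set `include_bias = TRUE` to penalise bias
#' vectors as well.
#'
#' @param base_loss Scalar unregularised loss.
#' @param parameters Named list of numeric matrices; entries whose names end
#'   in `"_W"` are treated as weights, `"_b"` as biases.
#' @param strength Non-negative regularisation strength.
#' @param include_bias Penalise bias terms too? Default `FALSE`.
#' @return Scalar regularised loss.
#' @export
l2_regularized_loss <- function(base_loss, parameters, strength,
                                include_bias = FALSE) {
  if (strength < 0) stop("'strength' must be >= 0", call. = FALSE)
  keep <- if (include_bias) names(parameters) else {
    grep("_W$", names(parameters), value = TRUE)
  }
  ssq <- sum(vapply(parameters[keep], function(p) sum(p^2), numeric(1)))
  base_loss + strength / 2 * ssq
}
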