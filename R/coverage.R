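# Vegetation coverage via a multinomial maximum-entropy (softmax) pixel
# classifier over the 9 color features. The model family is L2-penalized
# multinomial logistic regression on standardized features; the fit is the
# penalized maximum-likelihood estimate, obtained here by BFGS on the convex
# objective (any convex solver reaching the same optimum is equivalent).

#' Assemble a training set of labeled pixel colors
#'
#' @param labels character/factor vector of class labels, one per pixel.
#' @param r,g,b intensities in 0-255, one per pixel.
#' @return a `training_set` with 2-5 classes, each with at least one sample.
#' @export
training_set <- function(labels, r, g, b) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2L || length(classes) > 5L) {
    stop_plotpheno("bad_training",
                   "between 2 and 5 classes required, got ", length(classes))
  }
  if (length(labels) != length(r)) {
    stop_plotpheno("bad_training", "labels and colors differ in length")
  }
  structure(list(classes = classes, labels = labels,
                 features = color_features(r, g, b)),
            class = "training_set")
}

#' Read training samples from CSV
#'
#' Expects columns `class_label,r,g,b`, one row per marked pixel.
#'
#' @param path CSV file path.
#' @return a `training_set`.
#' @export
read_training_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class_label", "r", "g", "b")
  if (!all(need %in% names(df))) {
    stop_plotpheno("bad_training", "training CSV needs columns ",
                   paste(need, collapse = ","))
  }
  training_set(df$class_label, df$r, df$g, df$b)
}

softmax_rows <- function(scores) {
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

# Penalized negative log-likelihood and gradient. W is a (p+1) x K matrix
# (row 1 = intercepts, unpenalized); objective is
#   -(1/N) sum log p(y_i) + (l2/2) * sum(W[-1, ]^2)
maxent_obj <- function(w, X1, Y, l2) {
  K <- ncol(Y)
  W <- matrix(w, ncol = K)
  P <- softmax_rows(X1 %*% W)
  n <- nrow(X1)
  nll <- -sum(log(pmax(P[Y == 1], 1e-300))) / n
  nll + l2 / 2 * sum(W[-1L, ]^2)
}

maxent_grad <- function(w, X1, Y, l2) {
  K <- ncol(Y)
  W <- matrix(w, ncol = K)
  P <- softmax_rows(X1 %*% W)
  n <- nrow(X1)
  G <- crossprod(X1, P - Y) / n
  G[-1L, ] <- G[-1L, ] + l2 * W[-1L, ]
  as.vector(G)
}

#' Train the coverage classifier
#'
#' Fits the L2-penalized multinomial logistic (maximum-entropy) model on the
#' standardized 9-dimensional color features by quasi-Newton maximization of
#' the penalized log-likelihood. The optimum is unique up to the softmax
#' gauge (the ridge penalty pins it down), so the fit is deterministic; the
#' `seed` argument is accepted for interface stability.
#'
#' @param training a `training_set`.
#' @param l2_strength ridge penalty on the (standardized-scale) weights;
#'   intercepts are not penalized. Default `1e-4`.
#' @param vegetation_classes subset of class labels counted as vegetation.
#' @param seed unused by the deterministic solver; kept for reproducibility
#'   contracts.
#' @return a `coverage_model`.
#' @export
train_model <- function(training, l2_strength = 1e-4,
                        vegetation_classes = character(0), seed = 17L) {
  stopifnot(inherits(training, "training_set"))
  classes <- training$classes
  if (!all(vegetation_classes %in% classes)) {
    stop_plotpheno("bad_training",
                   "vegetation_classes must be a subset of the class labels")
  }
  counts <- table(factor(training$labels, levels = classes))
  if (any(counts == 0L)) {
    stop_plotpheno("bad_training", "every class needs at least one sample")
  }
  X <- training$features
  mu <- colMeans(X)
  sigma <- apply(X, 2L, stats::sd)
  sigma[sigma < 1e-12] <- 1   # constant features carry no information
  Xs <- sweep(sweep(X, 2L, mu), 2L, sigma, `/`)
  X1 <- cbind(1, Xs)
  Y <- outer(training$labels, classes, `==`) * 1
  K <- length(classes)
  w0 <- numeric(ncol(X1) * K)
  opt <- stats::optim(w0, maxent_obj, maxent_grad, X1 = X1, Y = Y,
                      l2 = l2_strength, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-14))
  W <- matrix(opt$par, ncol = K,
              dimnames = list(c("intercept", colnames(X)), classes))
  structure(list(classes = classes, weights = W, feature_means = mu,
                 feature_scales = sigma,
                 vegetation_classes = vegetation_classes,
                 l2_strength = l2_strength, converged = opt$convergence == 0L),
            class = "coverage_model")
}

#' Class probabilities for raw RGB pixels
#'
#' @param model a `coverage_model`.
#' @param r,g,b intensities in 0-255.
#' @return a matrix of per-class probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, r, g, b) {
  X <- color_features(r, g, b)
  Xs <- sweep(sweep(X, 2L, model$feature_means), 2L, model$feature_scales, `/`)
  P <- softmax_rows(cbind(1, Xs) %*% model$weights)
  colnames(P) <- model$classes
  P
}

#' Classify the pixels of an orthomosaic under a mask
#'
#' Assigns each masked, valid pixel its maximum-probability class; ties
#' break toward the earlier class in the model's class order. Invalid
#' pixels stay unlabeled.
#'
#' @param model a `coverage_model`.
#' @param ortho an `ortho_image`.
#' @param mask logical matrix of pixels to classify (defaults to all).
#' @return an integer matrix of class indices (into `model$classes`), `NA`
#'   outside the mask or where the image is invalid.
#' @export
classify_pixels <- function(model, ortho, mask = NULL) {
  stopifnot(inherits(model, "coverage_model"), inherits(ortho, "ortho_image"))
  if (is.null(mask)) {
    mask <- matrix(TRUE, ortho$grid$n_rows, ortho$grid$n_cols)
  }
  sel <- mask & ortho$valid
  out <- matrix(NA_integer_, ortho$grid$n_rows, ortho$grid$n_cols)
  idx <- which(sel)
  if (length(idx) == 0L) return(out)
  P <- predict_proba(model, ortho$r[idx], ortho$g[idx], ortho$b[idx])
  out[idx] <- max.col(P, ties.method = "first")
  out
}

#' Per-class fractions and vegetation coverage
#'
#' @param class_map integer class-index matrix from [classify_pixels()].
#' @param model the `coverage_model` (for class names and the vegetation
#'   set).
#' @param mask optional logical matrix restricting the tally.
#' @return a list with `fractions` (named, sums to 1 over labeled pixels),
#'   `coverage` (sum of vegetation-class fractions), and `n_labeled`.
#' @export
class_fractions <- function(class_map, model, mask = NULL) {
  labs <- if (is.null(mask)) class_map[!is.na(class_map)] else
    class_map[mask & !is.na(class_map)]
  if (length(labs) == 0L) {
    stop_plotpheno("no_labeled_pixels", "no labeled pixels to tally")
  }
  counts <- tabulate(labs, nbins = length(model$classes))
  fr <- counts / length(labs)
  names(fr) <- model$classes
  list(fractions = fr,
       coverage = sum(fr[model$classes %in% model$vegetation_classes]),
       n_labeled = length(labs))
}

#' Save / load a coverage model as JSON
#'
#' @param model a `coverage_model`.
#' @param path JSON file path.
#' @return `write_coverage_model`: path, invisibly; `read_coverage_model`:
#'   a `coverage_model`.
#' @export
write_coverage_model <- function(model, path) {
  jsonlite::write_json(list(
    classes = model$classes,
    weights = model$weights,
    feature_means = model$feature_means,
    feature_scales = model$feature_scales,
    vegetation_classes = model$vegetation_classes,
    l2_strength = model$l2_strength), path, digits = NA)
  invisible(path)
}

#' @rdname write_coverage_model
#' @export
read_coverage_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(obj$weights)
  colnames(W) <- obj$classes
  structure(list(classes = obj$classes, weights = W,
                 feature_means = obj$feature_means,
                 feature_scales = obj$feature_scales,
                 vegetation_classes = as.character(obj$vegetation_classes),
                 l2_strength = obj$l2_strength, converged = TRUE),
            class = "coverage_model")
}
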