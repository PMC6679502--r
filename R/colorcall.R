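# Colorimetric endpoint caller.
#
# The instrument's original CNN readout is replaced by a ridge-regularized
# logistic model on hand-crafted colour features: the task is two-class
# colour discrimination on a 30x30 patch, which linear colour statistics
# solve without a GPU or pretrained weights.

FEATURE_NAMES <- c("hue_cos_mean", "hue_sin_mean", "hue_sd_deg",
                   "sat_mean", "sat_sd", "val_mean", "val_sd",
                   "r_mean", "g_mean", "b_mean", "blue_red_ratio")

#' Extract colour features from an ROI image
#'
#' Hue/saturation/value statistics over the ROI plus per-channel means and
#' a blue-to-red ratio. Hue is an angle, so its mean is represented by the
#' (cos, sin) pair of the circular mean direction and its spread by the
#' circular standard deviation in degrees.
#'
#' @param roi an [generate_roi()] image, or a bare 30x30x3 array.
#' @return a named numeric feature vector.
#' @export
extract_features <- function(roi) {
  px <- if (inherits(roi, "roi_image")) roi$pixels else roi
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L ||
      dim(px)[1] != ROI_SIZE || dim(px)[2] != ROI_SIZE) {
    stop_invalid("ROI must be a ", ROI_SIZE, "x", ROI_SIZE, "x3 pixel array")
  }
  r <- as.vector(px[, , 1]); g <- as.vector(px[, , 2]); b <- as.vector(px[, , 3])
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  h_rad <- hsv[1, ] * 2 * pi
  s <- hsv[2, ]; v <- hsv[3, ]
  cbar <- mean(cos(h_rad)); sbar <- mean(sin(h_rad))
  rbar <- sqrt(cbar^2 + sbar^2)
  hue_sd <- if (rbar >= 1) 0 else sqrt(-2 * log(max(rbar, 1e-12))) * 180 / pi
  out <- c(cbar, sbar, hue_sd,
           mean(s), stats::sd(s), mean(v), stats::sd(v),
           mean(r) / 255, mean(g) / 255, mean(b) / 255,
           (mean(b) + 1) / (mean(r) + 1))
  names(out) <- FEATURE_NAMES
  out
}

feature_matrix <- function(rois) {
  t(vapply(rois, extract_features, numeric(length(FEATURE_NAMES))))
}

#' Train the colorimetric classifier
#'
#' Ridge-regularized logistic regression on [extract_features()] output.
#' Features are standardized with training-set statistics only;
#' zero-variance features get unit scale. Deterministic for fixed data and
#' seed.
#'
#' @param train a list of labelled [generate_roi()] images, or a
#'   `labeled_dataset` (its `train` split is used).
#' @param seed integer seed stored as training metadata.
#' @param lambda ridge penalty of the logistic fit.
#' @param threshold decision threshold on the positive-class score.
#' @return an object of class `color_classifier`.
#' @export
train_classifier <- function(train, seed = 1, lambda = 1e-2,
                             threshold = 0.5) {
  if (inherits(train, "labeled_dataset")) train <- train$train
  if (!is.list(train) || length(train) < 2L) {
    stop_invalid("need at least two labelled training images")
  }
  check_number(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  labels <- vapply(train, function(r) r$label, character(1))
  if (length(unique(labels)) < 2L) {
    stop_invalid("training set must contain both classes")
  }
  x <- feature_matrix(train)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  y <- factor(labels, levels = c("negative", "positive"))
  fit <- with_seed(seed,
    glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE))
  beta <- as.numeric(fit$beta[, 1])
  structure(
    list(center = center, scale = scale, weights = beta,
         bias = as.numeric(fit$a0[1]), threshold = threshold,
         lambda = lambda, feature_names = FEATURE_NAMES,
         n_train = length(train), seed = seed),
    class = "color_classifier"
  )
}

#' @export
print.color_classifier <- function(x, ...) {
  cat(sprintf(
    "Colorimetric logistic classifier (%d features, n_train = %d, lambda = %g)\n",
    length(x$weights), x$n_train, x$lambda))
  invisible(x)
}

#' Classify one ROI image
#'
#' Score is the logistic posterior for the positive (sky-blue) class; the
#' label is positive when `score >= threshold` — a tie at the threshold is
#' called positive, the fail-safe direction for a detection assay.
#'
#' @param model a fitted [train_classifier()] model.
#' @param roi an ROI image or 30x30x3 array.
#' @return a list with `label` and `score`.
#' @export
classify <- function(model, roi) {
  if (!inherits(model, "color_classifier")) {
    stop_invalid("model is not a fitted color_classifier")
  }
  f <- extract_features(roi)
  z <- (f - model$center) / model$scale
  # out-of-distribution patches (e.g. perfectly uniform colour) can land
  # many training sds away on variance features; clip so mean-colour
  # features keep deciding the call
  z <- pmin(pmax(z, -3), 3)
  score <- stats::plogis(model$bias + sum(model$weights * z))
  list(label = if (score >= model$threshold) "positive" else "negative",
       score = score)
}

#' Evaluate the classifier on a labelled test set
#'
#' @param model a fitted [train_classifier()] model.
#' @param test a list of labelled ROI images, or a `labeled_dataset`
#'   (its `test` split is used).
#' @return a list with `accuracy`, `n`, and `confusion` (2x2 table,
#'   truth in rows, call in columns).
#' @export
evaluate <- function(model, test) {
  if (inherits(test, "labeled_dataset")) test <- test$test
  if (!is.list(test) || length(test) == 0L) {
    stop_invalid("test set must be non-empty")
  }
  truth <- factor(vapply(test, function(r) r$label, character(1)),
                  levels = c("negative", "positive"))
  call <- factor(vapply(test, function(r) classify(model, r)$label,
                        character(1)),
                 levels = c("negative", "positive"))
  confusion <- table(truth = truth, call = call)
  list(accuracy = mean(truth == call), n = length(test),
       confusion = confusion)
}

#' Serialize a classifier to JSON
#'
#' @param model a [train_classifier()] model.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "color_classifier"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier from JSON
#'
#' @param path JSON file written by [write_classifier()].
#' @return a `color_classifier`.
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$center <- stats::setNames(as.numeric(obj$center), obj$feature_names)
  obj$scale <- stats::setNames(as.numeric(obj$scale), obj$feature_names)
  structure(obj, class = "color_classifier")
}
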