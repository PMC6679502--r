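test_that("features of a uniform image match the closed-form HSV conversion", {
  roi <- uniform_roi(c(110, 180, 230))
  f <- extract_features(roi)
  # analytic HSV of (110, 180, 230): v = max/255, s = (max-min)/max
  expect_equal(unname(f["sat_mean"]), (230 - 110) / 230)
  expect_equal(unname(f["val_mean"]), 230 / 255)
  expect_equal(unname(f["sat_sd"]), 0)
  expect_equal(unname(f["val_sd"]), 0)
  expect_equal(unname(f["hue_sd_deg"]), 0)
  h <- as.numeric(grDevices::rgb2hsv(110, 180, 230,
                                     maxColorValue = 255)[1]) * 2 * pi
  expect_equal(unname(f["hue_cos_mean"]), cos(h))
  expect_equal(unname(f["hue_sin_mean"]), sin(h))
  expect_equal(unname(f["blue_red_ratio"]), 231 / 111)
})

test_that("achromatic images have zero saturation", {
  f <- extract_features(uniform_roi(c(128, 128, 128)))
  expect_equal(unname(f["sat_mean"]), 0)
})

test_that("features are invariant to ROI rotation", {
  roi <- generate_roi("positive", color_model(), seed = 4)
  rotated <- roi
  rotated$pixels <- aperm(roi$pixels[, 30:1, ], c(2, 1, 3))  # 90 deg
  expect_equal(extract_features(roi), extract_features(rotated))
})

test_that("wrong shapes are rejected", {
  expect_error(extract_features(array(0L, dim = c(10, 10, 3))),
               class = "lodlamp_invalid_input")
  expect_error(extract_features(matrix(0, 30, 30)),
               class = "lodlamp_invalid_input")
})

test_that("training separates noiseless classes perfectly and is deterministic", {
  m <- color_model(pixel_noise_sd = 0, illumination_gradient_max = 0,
                   hue_jitter_sd = 0, ambiguity = 0)
  d <- generate_dataset(20, 10, m, master_seed = 1)
  clf <- train_classifier(d, seed = 1)
  expect_equal(evaluate(clf, d$train)$accuracy, 1)
  clf2 <- train_classifier(d, seed = 1)
  expect_identical(clf$weights, clf2$weights)
})

test_that("randomly permuted labels give chance-level accuracy", {
  d <- generate_dataset(60, 40, color_model(), master_seed = 2)
  set.seed(123)
  shuffled <- d$train
  labs <- vapply(shuffled, `[[`, "", "label")
  labs <- sample(labs)
  for (i in seq_along(shuffled)) shuffled[[i]]$label <- labs[i]
  clf <- train_classifier(shuffled, seed = 2)
  acc <- evaluate(clf, d$test)$accuracy
  # binomial error around 0.5 at n = 40: 3 sigma ~ 0.24
  expect_gt(acc, 0.5 - 0.25)
  expect_lt(acc, 0.5 + 0.25)
})

test_that("single-class training sets are rejected", {
  m <- color_model()
  only_neg <- lapply(1:6, function(i) generate_roi("negative", m, i))
  expect_error(train_classifier(only_neg), class = "lodlamp_invalid_input")
})

test_that("prototype colours are called correctly; threshold ties go positive", {
  d <- generate_dataset(40, 10, color_model(), master_seed = 3)
  clf <- train_classifier(d, seed = 3)
  expect_equal(classify(clf, uniform_roi(c(40, 40, 120)))$label, "negative")
  expect_equal(classify(clf, uniform_roi(c(110, 180, 230)))$label, "positive")
  # a null model scores exactly 0.5 everywhere: tie must be positive
  null_model <- clf
  null_model$weights <- rep(0, length(clf$weights))
  null_model$bias <- 0
  res <- classify(null_model, uniform_roi(c(40, 40, 120)))
  expect_equal(res$score, 0.5)
  expect_equal(res$label, "positive")
})

test_that("score rises monotonically when mixing a negative toward positive", {
  d <- generate_dataset(40, 10, color_model(), master_seed = 4)
  clf <- train_classifier(d, seed = 4)
  mix <- seq(0, 1, by = 0.1)
  scores <- vapply(mix, function(a) {
    col <- (1 - a) * c(40, 40, 120) + a * c(110, 180, 230)
    classify(clf, uniform_roi(round(col)))$score
  }, 0)
  expect_true(all(diff(scores) > -1e-9))
  expect_lt(scores[1], clf$threshold)
  expect_gt(scores[11], clf$threshold)
})

test_that("evaluate reports exact accuracy and consistent confusion counts", {
  d <- generate_dataset(40, 30, color_model(), master_seed = 5)
  clf <- train_classifier(d, seed = 5)
  res <- evaluate(clf, d)
  expect_equal(sum(res$confusion), 30)
  expect_equal(res$accuracy,
               sum(diag(res$confusion)) / sum(res$confusion))
  truth <- table(vapply(d$test, `[[`, "", "label"))
  expect_equal(as.numeric(rowSums(res$confusion)), as.numeric(truth))
  expect_error(evaluate(clf, list()), class = "lodlamp_invalid_input")
})

test_that("threshold sweep yields a monotone non-increasing false-positive rate", {
  d <- generate_dataset(40, 40, color_model(ambiguity = 0.9), master_seed = 6)
  clf <- train_classifier(d, seed = 6)
  scores <- vapply(d$test, function(r) classify(clf, r)$score, 0)
  truth <- vapply(d$test, `[[`, "", "label")
  fpr <- vapply(seq(0, 1, by = 0.05), function(th) {
    mean(scores[truth == "negative"] >= th)
  }, 0)
  expect_true(all(diff(fpr) <= 0))
})

test_that("accuracy does not increase with generator ambiguity", {
  # 5 ambiguity levels x 10 seeds; totals must be non-increasing up to
  # sampling error (one misclassified image of 200)
  levels <- c(0.15, 0.7, 0.9, 0.99, 1)
  mean_acc <- vapply(levels, function(a) {
    accs <- vapply(1:10, function(s) {
      d <- generate_dataset(30, 20, color_model(ambiguity = a),
                            master_seed = s)
      evaluate(train_classifier(d, seed = s), d)$accuracy
    }, 0)
    mean(accs)
  }, 0)
  expect_true(all(diff(mean_acc) <= 1 / 200 + 1e-9))
  expect_lt(mean_acc[5], 0.75)   # full ambiguity is chance level
})

test_that("classifiers round-trip through JSON", {
  d <- generate_dataset(20, 10, color_model(), master_seed = 7)
  clf <- train_classifier(d, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, path)
  back <- read_classifier(path)
  roi <- d$test[[3]]
  expect_equal(classify(back, roi)$score, classify(clf, roi)$score)
  expect_equal(back$weights, clf$weights)
})
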