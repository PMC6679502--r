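# Synthetic HNB reaction-image generator.
#
# Hydroxy naphthol blue stains the LAMP mix indigo; a positive reaction
# sequesters Mg2+ into magnesium pyrophosphate and the dye shifts to
# sky-blue. The generator emits labelled 30x30 RGB regions of interest
# (ROIs) emulating that readout under camera noise, illumination gradients
# across the detection chamber, per-image hue jitter, and an "ambiguity"
# mixing parameter standing in for partial reactions.

ROI_SIZE <- 30L

#' Colour model of the synthetic HNB readout
#'
#' @param negative_rgb 8-bit RGB triple of the indigo (negative) base.
#' @param positive_rgb 8-bit RGB triple of the sky-blue (positive) base.
#' @param pixel_noise_sd per-pixel Gaussian noise sd, 8-bit units.
#' @param illumination_gradient_max maximum relative amplitude of the
#'   random linear illumination gradient (fraction of signal).
#' @param hue_jitter_sd per-image hue jitter sd, degrees.
#' @param ambiguity in \[0, 1\]: mixes each class toward the other;
#'   at 1 both classes share the same expected colour.
#' @return an object of class `color_model`.
#' @export
color_model <- function(negative_rgb = c(40, 40, 120),
                        positive_rgb = c(110, 180, 230),
                        pixel_noise_sd = 8,
                        illumination_gradient_max = 0.15,
                        hue_jitter_sd = 4,
                        ambiguity = 0.15) {
  for (nm in c("negative_rgb", "positive_rgb")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3L || any(v < 0) || any(v > 255)) {
      stop_invalid(nm, " must be an RGB triple in [0, 255]")
    }
  }
  if (all(negative_rgb == positive_rgb)) {
    stop_invalid("base colours must be distinct")
  }
  check_number(pixel_noise_sd, "pixel_noise_sd", lower = 0)
  check_number(illumination_gradient_max, "illumination_gradient_max",
               lower = 0)
  check_number(hue_jitter_sd, "hue_jitter_sd", lower = 0)
  check_number(ambiguity, "ambiguity", lower = 0, upper = 1)
  structure(
    list(negative_rgb = as.numeric(negative_rgb),
         positive_rgb = as.numeric(positive_rgb),
         pixel_noise_sd = pixel_noise_sd,
         illumination_gradient_max = illumination_gradient_max,
         hue_jitter_sd = hue_jitter_sd, ambiguity = ambiguity),
    class = "color_model"
  )
}

# hue rotation in HSV space preserving saturation and value;
# rgb is a 0-255 triple, degrees the signed rotation
rotate_hue <- function(rgb, degrees) {
  hsv <- grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  h <- (hsv[1] * 360 + degrees) %% 360
  s <- hsv[2]; v <- hsv[3]
  c6 <- h / 60
  sector <- floor(c6) %% 6
  chroma <- v * s
  xs <- chroma * (1 - abs(c6 %% 2 - 1))
  tbl <- list(c(chroma, xs, 0), c(xs, chroma, 0), c(0, chroma, xs),
              c(0, xs, chroma), c(xs, 0, chroma), c(chroma, 0, xs))
  (tbl[[sector + 1]] + (v - chroma)) * 255
}

#' Generate one labelled synthetic ROI image
#'
#' The labelled base colour is mixed toward the opposite class by
#' `ambiguity / 2` (so that `ambiguity = 1` collapses both classes onto
#' their midpoint), hue-jittered once per image, multiplied by a random
#' linear illumination gradient, and finally perturbed by per-pixel
#' Gaussian noise; pixel values are clipped to \[0, 255\] and rounded.
#'
#' @param label `"positive"` or `"negative"`.
#' @param model a [color_model()].
#' @param seed integer seed; generation is deterministic per seed.
#' @return an object of class `roi_image`: list with `pixels`
#'   (30x30x3 integer array), `label`, `seed`, `generator_params`.
#' @export
generate_roi <- function(label = c("negative", "positive"),
                         model = color_model(), seed = 1) {
  stopifnot(inherits(model, "color_model"))
  if (!is.character(label) || !label[1] %in% c("negative", "positive")) {
    stop_invalid("label must be 'positive' or 'negative'")
  }
  label <- label[1]
  check_number(seed, "seed")
  with_seed(seed, {
    base <- if (label == "negative") model$negative_rgb else model$positive_rgb
    other <- if (label == "negative") model$positive_rgb else model$negative_rgb
    a <- model$ambiguity
    col <- (1 - a / 2) * base + (a / 2) * other
    if (model$hue_jitter_sd > 0) {
      col <- rotate_hue(col, stats::rnorm(1, 0, model$hue_jitter_sd))
    }
    n <- ROI_SIZE
    # random linear illumination gradient, relative amplitude <= max
    theta <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0, model$illumination_gradient_max)
    ax <- seq(-1, 1, length.out = n)
    u <- (outer(ax, ax, function(x, y) cos(theta) * x + sin(theta) * y)) /
      sqrt(2)
    factor <- 1 + amp * u
    pixels <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) {
      plane <- col[ch] * factor
      if (model$pixel_noise_sd > 0) {
        plane <- plane + stats::rnorm(n * n, 0, model$pixel_noise_sd)
      }
      pixels[, , ch] <- plane
    }
    pixels <- round(pmin(pmax(pixels, 0), 255))
    storage.mode(pixels) <- "integer"
    structure(list(pixels = pixels, label = label, seed = seed,
                   generator_params = model),
              class = "roi_image")
  })
}

#' @export
print.roi_image <- function(x, ...) {
  m <- apply(x$pixels, 3, mean)
  cat(sprintf("ROI image 30x30, label %s, seed %d, mean RGB (%.1f, %.1f, %.1f)\n",
              x$label, x$seed, m[1], m[2], m[3]))
  invisible(x)
}

#' Generate a balanced labelled train/test dataset
#'
#' Class labels alternate negative/positive so both splits are balanced to
#' within one image; per-image child seeds derive deterministically from
#' the master seed, with disjoint streams for train and test.
#'
#' @param n_train,n_test image counts (defaults 100 and 30).
#' @param model a [color_model()].
#' @param master_seed master seed.
#' @return a list of class `labeled_dataset` with `train` and `test` lists
#'   of [generate_roi()] images, plus `master_seed` and `model`.
#' @export
generate_dataset <- function(n_train = 100, n_test = 30,
                             model = color_model(), master_seed = 1) {
  check_number(n_train, "n_train", lower = 1)
  check_number(n_test, "n_test", lower = 1)
  make_split <- function(n, stream_base) {
    lapply(seq_len(n), function(i) {
      lab <- if (i %% 2 == 1) "negative" else "positive"
      generate_roi(lab, model,
                   seed = child_seed(master_seed, stream_base + i))
    })
  }
  structure(
    list(train = make_split(n_train, 0L),
         test = make_split(n_test, 100000L),
         master_seed = master_seed, model = model),
    class = "labeled_dataset"
  )
}

#' Write an ROI image as a plain-text PPM (P3) file
#'
#' PPM P3 is lossless 8-bit RGB and plain text, so images round-trip
#' exactly and stay reviewable in a terminal.
#'
#' @param roi an [generate_roi()] image.
#' @param path output file path (conventionally `.ppm`).
#' @return `path`, invisibly.
#' @export
write_roi_ppm <- function(roi, path) {
  stopifnot(inherits(roi, "roi_image"))
  px <- roi$pixels
  n <- dim(px)[1]
  # interleave channels row-major: r g b r g b ...
  flat <- as.vector(aperm(px, c(3, 2, 1)))  # channel fastest, then col, row
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", sprintf("%d %d", n, n), "255"), con)
  writeLines(paste(flat, collapse = " "), con)
  invisible(path)
}

#' Read a plain-text PPM (P3) file back into a pixel array
#'
#' @param path PPM file written by [write_roi_ppm()].
#' @return a 30x30x3 integer array.
#' @export
read_roi_ppm <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tokens[1] != "P3") stop_invalid("not an ASCII PPM (P3) file")
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  vals <- as.integer(tokens[-(1:4)])
  px <- array(0L, dim = c(h, w, 3))
  arr <- array(vals, dim = c(3, w, h))
  aperm(arr, c(3, 2, 1))
}

#' Write a dataset to disk with a manifest
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (split in c("train", "test")) {
    imgs <- dataset[[split]]
    for (i in seq_along(imgs)) {
      fn <- sprintf("%s_%03d_%s.ppm", split, i, imgs[[i]]$label)
      write_roi_ppm(imgs[[i]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        filename = fn, split = split, label = imgs[[i]]$label,
        seed = imgs[[i]]$seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
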