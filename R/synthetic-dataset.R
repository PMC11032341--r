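# Procedurally generated shape/colour image dataset. Categories split into
# two super-categories: "A" categories are discriminable chiefly by hue
# (every A image shares a common pool of contours) while "B" categories are
# discriminable chiefly by contour (every B image draws its hue at random).
# This mirrors the animate/inanimate structure that the stream-deletion
# analysis exploits, with the diagnostic cue known by construction.

#' Specification of the synthetic shape/colour dataset
#'
#' @param n_categories even number of categories; the first half form
#'   super-category "A" (hue-diagnostic), the second half "B"
#'   (contour-diagnostic).
#' @param n_train_per_category,n_eval_per_category images per category in the
#'   disjoint train and eval splits.
#' @param image_size image side in pixels (>= 16; shapes need room to render).
#' @param noise_sd per-pixel Gaussian noise SD in [0,1] intensity units.
#' @param jitter list with `position` and `scale` (fractions of the image
#'   side / base radius) and `hue` (degrees) controlling per-image jitter of
#'   the diagnostic cue.
#' @param diagnosticity fraction in \[0.8, 1\] of between-category signal
#'   carried by the diagnostic cue: for A categories the non-diagnostic
#'   contour is randomized with this weight, for B categories the
#'   non-diagnostic hue is.
#' @param grayscale render grayscale images (hue information destroyed);
#'   mainly for validating that A categories then collapse to chance.
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed) and regenerates bit-identical images.
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_categories = 20, n_train_per_category = 100,
                         n_eval_per_category = 20, image_size = 64,
                         noise_sd = 0.02,
                         jitter = list(position = 0.08, scale = 0.1, hue = 10),
                         diagnosticity = 0.9, grayscale = FALSE, seed = 1) {
  .assert(n_categories %% 2 == 0 && n_categories >= 2,
          "n_categories must be an even integer >= 2")
  .assert(image_size >= 16,
          "image_size too small for shape rendering (need >= 16 px)")
  .assert(noise_sd >= 0 && noise_sd <= 1, "noise_sd must lie in [0, 1]")
  .assert(diagnosticity >= 0.8 && diagnosticity <= 1,
          "diagnosticity must lie in [0.8, 1]")
  structure(list(n_categories = as.integer(n_categories),
                 n_train_per_category = as.integer(n_train_per_category),
                 n_eval_per_category = as.integer(n_eval_per_category),
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 jitter = jitter, diagnosticity = diagnosticity,
                 grayscale = isTRUE(grayscale), seed = as.integer(seed)),
            class = "dataset_spec")
}

# Luminance-constant hue encoding: the foreground colour is mid-gray plus a
# chroma vector along the hue's zero-mean opponent direction, so every hue
# has pixel mean exactly 0.5. Hue diagnosticity is thereby orthogonal to
# luminance: a grayscale rendering destroys all hue information (and no
# stream can read colour-category identity out of brightness).
.hue_color <- function(hue_deg, chroma) {
  base <- .hsv_to_rgb(hue_deg, 1, 1)
  dir <- base - mean(base)
  dir <- dir / max(abs(dir))
  0.5 + chroma * dir
}

# HSV (h in degrees, s, v in [0,1]) -> RGB in [0,1]; vectorized over h.
.hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- c(v, q, p, p, t, v)[i + 1]
  g <- c(t, v, v, q, p, p)[i + 1]
  b <- c(p, p, t, v, v, q)[i + 1]
  c(r, g, b)
}

.shape_families <- c("blob", "star", "bar")

# Random contour parameters drawn uniformly over the generator's ranges.
.sample_shape <- function() {
  list(family = sample(.shape_families, 1),
       n_lobes = sample(3:8, 1),
       amplitude = stats::runif(1, 0.15, 0.45),
       aspect = stats::runif(1, 1.6, 3.2),
       rotation = stats::runif(1, 0, 180),
       phase = stats::runif(1, 0, 2 * pi))
}

# Blend contour parameters a -> b with weight w (w = 1 gives b).
.blend_shape <- function(a, b, w) {
  list(family = if (stats::runif(1) < w) b$family else a$family,
       n_lobes = as.integer(round(a$n_lobes + w * (b$n_lobes - a$n_lobes))),
       amplitude = a$amplitude + w * (b$amplitude - a$amplitude),
       aspect = a$aspect + w * (b$aspect - a$aspect),
       rotation = a$rotation + w * (b$rotation - a$rotation),
       phase = a$phase + w * (b$phase - a$phase))
}

# Radial profile r(phi)/r0 of a contour family (analytic mask rendering).
.radial_profile <- function(shape, phi) {
  if (shape$family == "blob") {
    1 + 0.5 * shape$amplitude * cos(2 * phi + shape$phase) +
      0.5 * shape$amplitude * cos(3 * phi + 2 * shape$phase)
  } else if (shape$family == "star") {
    1 + shape$amplitude * cos(shape$n_lobes * phi + shape$phase)
  } else {  # bar: anisotropically scaled ellipse
    a <- shape$aspect
    1 / sqrt((cos(phi) / a)^2 + (sin(phi) * a)^2)
  }
}

# Render one image: filled contour on a gray background, soft 1-px edge,
# additive Gaussian pixel noise, quantized to 8-bit levels.
.render_image <- function(shape, hue_deg, spec) {
  n <- spec$image_size
  jit <- spec$jitter
  cx <- n / 2 + stats::runif(1, -1, 1) * jit$position * n
  cy <- n / 2 + stats::runif(1, -1, 1) * jit$position * n
  r0 <- 0.30 * n * (1 + stats::runif(1, -1, 1) * jit$scale)
  rot <- shape$rotation * pi / 180

  x <- matrix(seq_len(n) - cx, n, n, byrow = TRUE)
  y <- matrix(seq_len(n) - cy, n, n)
  dist <- sqrt(x^2 + y^2)
  phi <- atan2(y, x) - rot
  edge <- .radial_profile(shape, phi) * r0
  alpha <- pmin(1, pmax(0, edge - dist + 0.5))   # soft edge over ~1 px

  col <- .hue_color(hue_deg, chroma = 0.42 + stats::runif(1, -0.04, 0.04))
  bg <- 0.25
  img <- array(0, dim = c(n, n, 3))
  for (c in 1:3) img[, , c] <- bg + alpha * (col[c] - bg)
  if (spec$grayscale) {
    gr <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    for (c in 1:3) img[, , c] <- gr
  }
  img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd), dim(img))
  img <- pmin(1, pmax(0, img))
  round(img * 255) / 255                          # 8-bit storage levels
}

# Category table: ids, super-category labels, per-category hue centres and
# contour parameters.
.make_category_table <- function(spec) {
  n <- spec$n_categories
  n_half <- n %/% 2
  shapes <- lapply(seq_len(n), function(i) .sample_shape())
  data.frame(
    category_id = seq_len(n),
    super_category = rep(c("A", "B"), each = n_half),
    hue_center = c(seq(0, 360, length.out = n_half + 1)[seq_len(n_half)],
                   (seq(0, 360, length.out = n_half + 1)[seq_len(n_half)] +
                      180 / n_half) %% 360),
    shape_family = vapply(shapes, `[[`, "", "family"),
    n_lobes = vapply(shapes, `[[`, 0L, "n_lobes"),
    amplitude = vapply(shapes, `[[`, 0, "amplitude"),
    aspect = vapply(shapes, `[[`, 0, "aspect"),
    rotation = vapply(shapes, `[[`, 0, "rotation"),
    phase = vapply(shapes, `[[`, 0, "phase"),
    diagnosticity = spec$diagnosticity,
    stringsAsFactors = FALSE
  )
}

.category_shape <- function(cat_row) {
  list(family = cat_row$shape_family, n_lobes = cat_row$n_lobes,
       amplitude = cat_row$amplitude, aspect = cat_row$aspect,
       rotation = cat_row$rotation, phase = cat_row$phase)
}

# Draw one image's hue and contour for a category under the diagnosticity
# rule: the diagnostic cue stays near the category value (small jitter), the
# non-diagnostic cue is randomized with weight d.
.sample_image_params <- function(cat_row, spec) {
  d <- spec$diagnosticity
  cat_shape <- .category_shape(cat_row)
  if (cat_row$super_category == "A") {
    hue <- cat_row$hue_center + stats::runif(1, -1, 1) * spec$jitter$hue
    shape <- .blend_shape(cat_shape, .sample_shape(), d)
  } else {
    hue <- cat_row$hue_center + stats::runif(1, -d * 180, d * 180)
    shape <- cat_shape
    shape$rotation <- shape$rotation + stats::runif(1, -10, 10)
    shape$amplitude <- shape$amplitude * stats::runif(1, 0.95, 1.05)
  }
  list(hue = hue %% 360, shape = shape)
}

#' Generate the synthetic shape/colour dataset
#'
#' Deterministic in (spec, seed): rerunning with the same spec reproduces
#' bit-identical images (and, if written, identical PNG files). Train and
#' eval splits are disjoint by construction (separate draws).
#'
#' @param spec a [dataset_spec()].
#' @param out_dir optional directory; when given, images are written as PNG
#'   files in a directory-of-class-folders layout
#'   (`<out_dir>/<split>/cat_<id>/img_<i>.png`) together with
#'   `categories.csv` and the deparsed spec.
#' @return object of class `shape_dataset`: list with `spec`, `categories`
#'   (the category table), `train` and `eval` (each `x` = (H, W, 3, N) float
#'   array in \[0,1\], `y` = integer category ids), and `dir`.
#' @export
generate_dataset <- function(spec, out_dir = NULL) {
  .assert(inherits(spec, "dataset_spec"), "spec must be a dataset_spec")
  res <- .with_seed(spec$seed, {
    categories <- .make_category_table(spec)
    gen_split <- function(n_per) {
      n_tot <- spec$n_categories * n_per
      x <- array(0, dim = c(spec$image_size, spec$image_size, 3, n_tot))
      y <- integer(n_tot)
      i <- 0L
      for (ci in seq_len(spec$n_categories)) {
        cat_row <- categories[ci, ]
        for (im in seq_len(n_per)) {
          i <- i + 1L
          p <- .sample_image_params(cat_row, spec)
          x[, , , i] <- .render_image(p$shape, p$hue, spec)
          y[i] <- cat_row$category_id
        }
      }
      list(x = x, y = y)
    }
    list(categories = categories,
         train = gen_split(spec$n_train_per_category),
         eval = gen_split(spec$n_eval_per_category))
  })
  ds <- structure(list(spec = spec, categories = res$categories,
                       train = res$train, eval = res$eval, dir = out_dir),
                  class = "shape_dataset")
  if (!is.null(out_dir)) .write_dataset(ds, out_dir)
  ds
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat(sprintf(paste0("<shape_dataset %d categories (A: %d, B: %d), ",
                     "%d train / %d eval per category, %dx%d px>\n"),
              x$spec$n_categories,
              sum(x$categories$super_category == "A"),
              sum(x$categories$super_category == "B"),
              x$spec$n_train_per_category, x$spec$n_eval_per_category,
              x$spec$image_size, x$spec$image_size))
  invisible(x)
}

.write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ds$categories, file.path(out_dir, "categories.csv"),
                   row.names = FALSE)
  writeLines(deparse(unclass(ds$spec)), file.path(out_dir, "spec.R"))
  for (split in c("train", "eval")) {
    xs <- ds[[split]]
    for (i in seq_along(xs$y)) {
      cdir <- file.path(out_dir, split, sprintf("cat_%03d", xs$y[i]))
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      j <- sum(xs$y[seq_len(i)] == xs$y[i])
      png::writePNG(aperm(xs$x[, , , i], c(1, 2, 3)),
                    file.path(cdir, sprintf("img_%04d.png", j)))
    }
  }
  invisible(out_dir)
}

#' Load a written shape dataset from disk
#'
#' Reads back the directory-of-class-folders PNG layout written by
#' [generate_dataset()].
#'
#' @param dir dataset directory.
#' @return a `shape_dataset` object.
#' @export
load_shape_dataset <- function(dir) {
  .assert(file.exists(file.path(dir, "categories.csv")),
          "not a dataset directory (categories.csv missing)")
  categories <- utils::read.csv(file.path(dir, "categories.csv"),
                                stringsAsFactors = FALSE)
  spec <- structure(eval(parse(text = readLines(file.path(dir, "spec.R")))),
                    class = "dataset_spec")
  read_split <- function(split) {
    cdirs <- sort(list.dirs(file.path(dir, split), recursive = FALSE))
    xs <- list(); ys <- integer(0)
    for (cd in cdirs) {
      id <- as.integer(sub("cat_", "", basename(cd)))
      files <- sort(list.files(cd, pattern = "\\.png$", full.names = TRUE))
      for (f in files) {
        img <- png::readPNG(f)
        xs[[length(xs) + 1L]] <- img
        ys <- c(ys, id)
      }
    }
    n <- spec$image_size
    x <- array(0, dim = c(n, n, 3, length(xs)))
    for (i in seq_along(xs)) x[, , , i] <- xs[[i]]
    list(x = x, y = ys)
  }
  structure(list(spec = spec, categories = categories,
                 train = read_split("train"), eval = read_split("eval"),
                 dir = dir),
            class = "shape_dataset")
}

#' Select a fixed stimulus set for representational analysis
#'
#' Randomly selects `n_per_category` eval images per category, in category
#' order, reproducibly under `seed`. The same set should be reused across
#' all layers/streams being compared.
#'
#' @param dataset a `shape_dataset`.
#' @param n_per_category images per category (default 1).
#' @param seed integer seed.
#' @return list with `x` ((H, W, 3, N) array), `category_id` and
#'   `eval_index` (positions within the eval split).
#' @export
generate_rdm_stimulus_set <- function(dataset, n_per_category = 1, seed = 1) {
  .assert(inherits(dataset, "shape_dataset"), "dataset must be a shape_dataset")
  .assert(n_per_category >= 1 &&
            n_per_category <= dataset$spec$n_eval_per_category,
          "n_per_category exceeds available eval images")
  .with_seed(seed, {
    picks <- integer(0)
    for (id in dataset$categories$category_id) {
      avail <- which(dataset$eval$y == id)
      picks <- c(picks, sort(sample(avail, n_per_category)))
    }
    list(x = dataset$eval$x[, , , picks, drop = FALSE],
         category_id = dataset$eval$y[picks],
         eval_index = picks)
  })
}
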