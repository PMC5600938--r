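#' Stimulus configuration for digit clutter / digit debris scenes
#'
#' Defines the generative model for one stimulus condition. Scenes are composed
#' at a high design resolution and then downsampled by area averaging to the
#' resolution presented to the network. Digit glyphs use one fixed built-in
#' typeface, at one fixed size, white ink on a black background; the only
#' variation within a condition is digit identity and (uniformly jittered)
#' position, plus the occluders.
#'
#' @param task `"debris"` (one target digit occluded by random digit fragments)
#'   or `"clutter"` (several overlapping target digits, all to be reported).
#' @param n_digits number of target digits per scene (clutter; 1 for debris).
#' @param n_fragments number of occluding fragments per scene (debris; the
#'   standard difficulty levels are 10, 30 and 50).
#' @param design_resolution side of the square canvas scenes are composed on,
#'   in pixels. Must be an integer multiple of `output_resolution`.
#' @param output_resolution side of the downsampled image fed to the network.
#' @param digit_size glyph height in design pixels.
#' @param jitter_extent half-side, in design pixels, of the central square from
#'   which digit centres are drawn uniformly. Must leave room for the glyph.
#' @param fragment_size_range length-2 numeric, min/max side (design pixels) of
#'   the square crops used as debris fragments. The default, 0.2 to 0.4 of the
#'   glyph height, yields a mean occlusion of roughly 10/30/45 percent of the
#'   target's ink at 10/30/50 fragments — dense debris that still leaves the
#'   digit recoverable.
#' @param font_id identifier of the built-in typeface (only `"blockface"`).
#' @param seed base RNG seed recorded in manifests and used by
#'   [generate_dataset()].
#'
#' @return An object of class `stimulus_config` (a list).
#' @examples
#' cfg <- stimulus_config(task = "debris", n_fragments = 30, seed = 1)
#' cfg
#' @export
stimulus_config <- function(task = c("debris", "clutter"),
                            n_digits = if (task == "clutter") 3L else 1L,
                            n_fragments = if (task == "debris") 10L else 0L,
                            design_resolution = 512L,
                            output_resolution = 32L,
                            digit_size = 320L,
                            jitter_extent = 80L,
                            fragment_size_range = NULL,
                            font_id = "blockface",
                            seed = 1L) {
  task <- match.arg(task)
  if (design_resolution %% output_resolution != 0) {
    stop("`design_resolution` must be an integer multiple of `output_resolution`.")
  }
  if (n_digits < 1) stop("`n_digits` must be at least 1.")
  if (n_fragments < 0) stop("`n_fragments` must be non-negative.")
  if (font_id != "blockface") stop("unknown `font_id`: ", font_id)
  if (is.null(fragment_size_range)) {
    fragment_size_range <- round(c(0.2, 0.4) * digit_size)
  }
  if (any(fragment_size_range > design_resolution)) {
    stop("`fragment_size_range` exceeds the canvas size.")
  }
  if (fragment_size_range[1] > fragment_size_range[2] || fragment_size_range[1] < 1) {
    stop("`fragment_size_range` must be an increasing pair of positive sizes.")
  }
  g <- glyph_bitmap(0)
  glyph_w <- round(digit_size * ncol(g) / nrow(g))
  centre <- (design_resolution + 1) / 2
  jb <- c(
    xmin = centre - jitter_extent, xmax = centre + jitter_extent,
    ymin = centre - jitter_extent, ymax = centre + jitter_extent
  )
  half_h <- ceiling(digit_size / 2)
  half_w <- ceiling(glyph_w / 2)
  if (jb["xmin"] - half_w < 0 || jb["xmax"] + half_w > design_resolution + 1 ||
      jb["ymin"] - half_h < 0 || jb["ymax"] + half_h > design_resolution + 1) {
    stop("`jitter_extent` too large: glyphs would not fit on the canvas.")
  }
  structure(
    list(
      task = task,
      n_digits = as.integer(n_digits),
      n_fragments = as.integer(n_fragments),
      design_resolution = as.integer(design_resolution),
      output_resolution = as.integer(output_resolution),
      digit_size = as.integer(digit_size),
      jitter_bounds = jb,
      fragment_size_range = as.numeric(fragment_size_range),
      font_id = font_id,
      seed = as.integer(seed)
    ),
    class = "stimulus_config"
  )
}

#' @export
print.stimulus_config <- function(x, ...) {
  lev <- if (x$task == "debris") {
    paste0(x$n_fragments, " fragments")
  } else {
    paste0(x$n_digits, " digits")
  }
  cat(sprintf(
    "<stimulus_config> %s (%s), %dpx design -> %dpx output, seed %d\n",
    x$task, lev, x$design_resolution, x$output_resolution, x$seed
  ))
  invisible(x)
}

# Short condition tag used in manifests, e.g. "debris50", "clutter3".
condition_tag <- function(config) {
  if (config$task == "debris") {
    paste0("debris", config$n_fragments)
  } else {
    paste0("clutter", config$n_digits)
  }
}

#' Render a single digit glyph on the design canvas
#'
#' Draws one glyph of the configured typeface and size, centred at `position`,
#' on an otherwise empty design-resolution canvas. Ink pixels are 1, background
#' is 0.
#'
#' @param class digit class, 0-9.
#' @param position numeric `c(x, y)` centre in design pixels; must lie inside
#'   the configuration's jitter bounds.
#' @param config a [stimulus_config()].
#' @return A `design_resolution` x `design_resolution` matrix in `[0, 1]`.
#' @examples
#' cfg <- stimulus_config()
#' img <- render_digit(3, c(256, 256), cfg)
#' sum(img)  # ink pixel count
#' @export
render_digit <- function(class, position, config) {
  if (!(length(class) == 1 && class %in% 0:9)) {
    stop("`class` must be a single digit 0-9.")
  }
  jb <- config$jitter_bounds
  if (position[1] < jb["xmin"] || position[1] > jb["xmax"] ||
      position[2] < jb["ymin"] || position[2] > jb["ymax"]) {
    stop("`position` lies outside the jitter bounds.")
  }
  canvas <- matrix(0, config$design_resolution, config$design_resolution)
  paste_ink(canvas, glyph_scaled(class, config$digit_size), position)
}

# Linear canvas indices of the ink pixels of patch `p` pasted with its
# top-left corner at (top, left) on a canvas with `n` rows. Compositing is a
# union of ink: all ink shares one colour, so pasting only ink pixels is
# visually identical to opaque layering, while a separate visibility map
# tracks depth order. Callers assign `canvas[idx] <- 1` in their own scope so
# the canvas is modified in place rather than copied per paste.
ink_indices <- function(p, top, left, n) {
  ink <- which(p > 0)
  pr <- (ink - 1L) %% nrow(p)
  pc <- (ink - 1L) %/% nrow(p)
  (top + pr) + (left + pc - 1L) * n
}

# Placement of a patch centred at c(x, y): top-left corner, with bounds check.
patch_corner <- function(p, centre, n) {
  centre <- as.numeric(centre)
  top <- round(centre[2] - nrow(p) / 2) + 1
  left <- round(centre[1] - ncol(p) / 2) + 1
  if (top < 1 || left < 1 || top + nrow(p) - 1 > n || left + ncol(p) - 1 > n) {
    stop("glyph does not fit on the canvas at this position.")
  }
  c(top = top, left = left)
}

# Paste the ink (value 1) of patch `p` onto `canvas`, centred at c(x, y).
paste_ink <- function(canvas, p, centre) {
  at <- patch_corner(p, centre, nrow(canvas))
  canvas[ink_indices(p, at["top"], at["left"], nrow(canvas))] <- 1
  canvas
}

#' Compose a digit-clutter scene
#'
#' Draws `n_digits` digits with pairwise-distinct classes, placed sequentially
#' at positions drawn uniformly from the jitter bounds. Later digits are nearer:
#' at any pixel covered by several digits' ink, the digit placed last owns the
#' pixel (returned in `visible`). The label set is the set of classes present.
#'
#' Uses the current R RNG stream; seed it (or use [generate_dataset()]) for
#' reproducibility.
#'
#' @param config a [stimulus_config()] with `task = "clutter"` (or any config;
#'   `n_digits` governs the scene).
#' @return A list with elements `scene` (targets, positions, depth order),
#'   `image` (design-resolution matrix) and `visible` (integer matrix of the
#'   owning placement index per pixel, 0 for background).
#' @examples
#' set.seed(1)
#' s <- compose_clutter(stimulus_config(task = "clutter", n_digits = 3))
#' s$scene$targets
#' @export
compose_clutter <- function(config) {
  n <- config$n_digits
  if (n < 1) stop("`n_digits` must be >= 1.")
  if (n > 10) stop("at most 10 distinct digit classes are available.")
  jb <- config$jitter_bounds
  classes <- sample(0:9, n, replace = FALSE)
  xs <- runif(n, jb["xmin"], jb["xmax"])
  ys <- runif(n, jb["ymin"], jb["ymax"])
  res <- config$design_resolution
  canvas <- matrix(0, res, res)
  visible <- matrix(0L, res, res)
  for (i in seq_len(n)) {
    g <- glyph_scaled(classes[i], config$digit_size)
    at <- patch_corner(g, c(xs[i], ys[i]), res)
    idx <- ink_indices(g, at["top"], at["left"], res)
    canvas[idx] <- 1
    visible[idx] <- i
  }
  list(
    scene = list(
      targets = classes,
      positions = cbind(x = xs, y = ys),
      depth_order = seq_len(n),
      fragments = NULL
    ),
    image = canvas,
    visible = visible
  )
}

# Cached full-canvas render of each class at the canvas centre; debris
# fragments are cropped out of these.
centred_render <- function(class, config) {
  key <- paste0("c", class, "_", config$design_resolution, "_", config$digit_size)
  if (is.null(.font_cache[[key]])) {
    canvas <- matrix(0, config$design_resolution, config$design_resolution)
    centre <- rep((config$design_resolution + 1) / 2, 2)
    canvas <- paste_ink(canvas, glyph_scaled(class, config$digit_size), centre)
    .font_cache[[key]] <- canvas
  }
  .font_cache[[key]]
}

#' Compose a digit-debris scene
#'
#' Renders a single target digit at a jittered position, then overlays
#' `n_fragments` debris fragments: square crops taken from renders of uniformly
#' chosen digit classes (any of 0-9), at uniformly chosen offsets within the
#' source glyph's bounding box, pasted at uniform positions on the canvas.
#' Fragments add ink, so the target's features are swamped by features of
#' non-targets rather than deleted. The label is the single target class.
#'
#' @param config a [stimulus_config()]; `n_fragments` governs debris density.
#' @param target_class optional fixed target digit 0-9; sampled uniformly if
#'   `NULL`.
#' @return A list with `scene` (target, position, fragment records), `image`,
#'   `target_mask` and `debris_mask` (design-resolution binary matrices).
#' @examples
#' set.seed(1)
#' s <- compose_debris(stimulus_config(task = "debris", n_fragments = 10))
#' s$scene$targets
#' @export
compose_debris <- function(config, target_class = NULL) {
  if (config$n_fragments < 0) stop("`n_fragments` must be >= 0.")
  jb <- config$jitter_bounds
  if (is.null(target_class)) target_class <- sample(0:9, 1)
  if (!(length(target_class) == 1 && target_class %in% 0:9)) {
    stop("`target_class` must be a single digit 0-9.")
  }
  pos <- c(runif(1, jb["xmin"], jb["xmax"]), runif(1, jb["ymin"], jb["ymax"]))
  res <- config$design_resolution
  target_layer <- render_digit(target_class, pos, config)
  bb <- glyph_bbox(config)
  nf <- config$n_fragments
  if (nf > 0) {
    # All randomness is drawn here; the pixel pasting itself is delegated.
    cls <- sample(0:9, nf, replace = TRUE)
    side <- round(runif(nf, config$fragment_size_range[1],
                        config$fragment_size_range[2]))
    crop_top <- pmin(pmax(1, sample_range_vec(bb$top, bb$bottom - side + 1)),
                     res - side + 1)
    crop_left <- pmin(pmax(1, sample_range_vec(bb$left, bb$right - side + 1)),
                      res - side + 1)
    paste_top <- sample_range_vec(1, res - side + 1)
    paste_left <- sample_range_vec(1, res - side + 1)
    fragments <- tibble::tibble(
      class = cls, side = as.integer(side),
      crop_top = as.integer(crop_top), crop_left = as.integer(crop_left),
      paste_top = as.integer(paste_top), paste_left = as.integer(paste_left)
    )
    sources <- lapply(0:9, centred_render, config = config)
    spec_mat <- cbind(cls, side, crop_top, crop_left, paste_top, paste_left)
    storage.mode(spec_mat) <- "integer"
    pasted <- cpp_paste_fragments(target_layer, sources, spec_mat)
    canvas <- pasted$image
    debris <- pasted$debris
  } else {
    fragments <- NULL
    canvas <- target_layer
    debris <- matrix(0, res, res)
  }
  list(
    scene = list(
      targets = target_class,
      positions = matrix(pos, 1, 2, dimnames = list(NULL, c("x", "y"))),
      depth_order = 1L,
      fragments = fragments
    ),
    image = canvas,
    target_mask = target_layer,
    debris_mask = debris
  )
}

# Bounding box (rows/cols) of a glyph rendered at the canvas centre. All
# glyphs share the same box because the typeface is fixed-width.
glyph_bbox <- function(config) {
  h <- config$digit_size
  g <- glyph_bitmap(0)
  w <- ncol(glyph_scaled(0, h))
  centre <- (config$design_resolution + 1) / 2
  top <- round(centre - h / 2) + 1
  left <- round(centre - w / 2) + 1
  list(top = top, bottom = top + h - 1, left = left, right = left + w - 1)
}

# Uniform integer in [lo, hi]; returns lo when the range is degenerate.
sample_range <- function(lo, hi) {
  if (hi <= lo) return(lo)
  lo + floor(runif(1) * (hi - lo + 1))
}

# Vectorized uniform integers in [lo, hi_i]; degenerate ranges collapse to lo.
sample_range_vec <- function(lo, hi) {
  width <- pmax(0, hi - lo + 1)
  pmin(lo + floor(runif(length(hi)) * pmax(1, width)), pmax(lo, hi))
}

#' Downsample a design-resolution image by area averaging
#'
#' Reduces a design-resolution scene to the output resolution by averaging
#' non-overlapping square blocks (exact area-average antialiasing for integer
#' reduction factors). Mean-preserving: a constant image maps to the same
#' constant.
#'
#' @param image design-resolution matrix.
#' @param output_resolution target side length; the reduction factor
#'   `nrow(image) / output_resolution` must be an integer.
#' @return An `output_resolution` x `output_resolution` matrix in `[0, 1]`.
#' @export
downsample <- function(image, output_resolution = 32L) {
  f <- nrow(image) / output_resolution
  if (f != round(f)) stop("reduction factor must be an integer.")
  if (f == 1) return(image)
  g <- rep(seq_len(output_resolution), each = f)
  out <- t(rowsum(t(rowsum(image, g)), g) / (f * f))
  dimnames(out) <- NULL
  out
}

#' Fit and apply pixel-wise normalization
#'
#' `fit_normalization()` computes, for every pixel position, the mean and
#' standard deviation over a (training) dataset. `normalize()` maps each pixel
#' to `(x - mean) / sd`; positions whose training standard deviation is zero
#' map to zero. Statistics must be fitted on the training split only and are
#' then applied to every split.
#'
#' @param dataset a dataset from [generate_dataset()] (or any object with an
#'   `images` array of dimension `res x res x n`).
#' @return `fit_normalization()`: an object of class `blt_norm_stats` with
#'   per-pixel `mean` and `sd` matrices; `normalize()`: an image matrix or
#'   image array of the same shape as its input.
#' @examples
#' cfg <- stimulus_config(task = "debris", n_fragments = 10, seed = 7)
#' tr <- generate_dataset(cfg, n_images = 20, role = "train")
#' st <- fit_normalization(tr)
#' x <- normalize(tr$images[, , 1], st)
#' @export
fit_normalization <- function(dataset) {
  imgs <- dataset$images
  d <- dim(imgs)
  m <- matrix(imgs, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / max(1, d[3] - 1))
  structure(
    list(
      mean = matrix(mu, d[1], d[2]),
      sd = matrix(s, d[1], d[2]),
      fitted_on = dataset$role %||% "unknown",
      n = d[3]
    ),
    class = "blt_norm_stats"
  )
}

#' @param x an image matrix, or an image array `res x res x n`.
#' @param stats a `blt_norm_stats` object from `fit_normalization()`.
#' @rdname fit_normalization
#' @export
normalize <- function(x, stats) {
  if (is.matrix(x)) {
    if (!all(dim(x) == dim(stats$mean))) {
      stop("image resolution does not match the normalization statistics.")
    }
    out <- (x - stats$mean) / ifelse(stats$sd == 0, 1, stats$sd)
    out[stats$sd == 0] <- 0
    return(out)
  }
  d <- dim(x)
  if (!all(d[1:2] == dim(stats$mean))) {
    stop("image resolution does not match the normalization statistics.")
  }
  sdv <- as.vector(ifelse(stats$sd == 0, 1, stats$sd))
  m <- (matrix(x, d[1] * d[2], d[3]) - as.vector(stats$mean)) / sdv
  m[as.vector(stats$sd == 0), ] <- 0
  array(m, d)
}

#' Add i.i.d. Gaussian pixel noise
#'
#' Adds zero-mean Gaussian noise with standard deviation `sigma` to an already
#' normalized image (unit-variance signal), giving a signal-to-noise ratio of
#' `1 / sigma`: `sigma = 1` gives SNR 1, `sigma = 2` gives SNR 0.5. The noise
#' is sampled once per image; the noisy image is then presented unchanged at
#' every time step.
#'
#' @param image normalized image matrix (or array of images).
#' @param sigma noise standard deviation, `>= 0`.
#' @return The noisy image(s), same shape as the input.
#' @export
add_gaussian_noise <- function(image, sigma) {
  if (sigma < 0) stop("`sigma` must be non-negative.")
  if (sigma == 0) return(image)
  image + array(rnorm(length(image), sd = sigma), dim(image))
}

#' Generate a stimulus dataset split
#'
#' Draws `n_images` scenes from the configured generative model, downsamples
#' them to the output resolution and assembles a labelled split. Generation is
#' a pure function of `(config, seed, role)`: each role gets its own derived
#' RNG stream, so the train/validation/test splits are mutually independent
#' and individually reproducible. The reference study sizes are 100,000
#' training, 10,000 validation and 10,000 test images per condition.
#'
#' @param config a [stimulus_config()].
#' @param n_images number of scenes to generate.
#' @param role `"train"`, `"val"` or `"test"`.
#' @param seed base seed; defaults to `config$seed`.
#' @param out_dir optional directory: if given, writes one 8-bit grayscale PNG
#'   per image plus a `manifest.csv` with columns
#'   `filename,labels,condition,seed` (labels semicolon-joined).
#' @return An object of class `blt_dataset`: list with `images`
#'   (`res x res x n` array of raw `[0,1]` pixel values), `labels` (list of
#'   integer class vectors), `manifest` (tibble), `role` and `config`.
#' @examples
#' cfg <- stimulus_config(task = "clutter", n_digits = 3, seed = 11)
#' ds <- generate_dataset(cfg, n_images = 5, role = "test")
#' ds$manifest
#' @export
generate_dataset <- function(config, n_images, role = c("train", "val", "test"),
                             seed = config$seed, out_dir = NULL) {
  role <- match.arg(role)
  if (n_images < 1) stop("`n_images` must be at least 1.")
  role_id <- match(role, c("train", "val", "test"))
  set.seed(derive_seed(seed, role_id, 7919L))
  res <- config$output_resolution
  images <- array(0, c(res, res, n_images))
  labels <- vector("list", n_images)
  tag <- condition_tag(config)
  for (i in seq_len(n_images)) {
    sc <- if (config$task == "debris") {
      compose_debris(config)
    } else {
      compose_clutter(config)
    }
    images[, , i] <- downsample(sc$image, res)
    labels[[i]] <- sort(as.integer(sc$scene$targets))
  }
  manifest <- tibble::tibble(
    filename = sprintf("%s_%s_%06d.png", tag, role, seq_len(n_images)),
    labels = vapply(labels, paste, "", collapse = ";"),
    condition = tag,
    seed = as.integer(seed)
  )
  ds <- structure(
    list(images = images, labels = labels, manifest = manifest,
         role = role, config = config),
    class = "blt_dataset"
  )
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' @export
print.blt_dataset <- function(x, ...) {
  cat(sprintf(
    "<blt_dataset> %s split, %d images (%dx%d), condition %s\n",
    x$role, length(x$labels), dim(x$images)[1], dim(x$images)[2],
    condition_tag(x$config)
  ))
  invisible(x)
}

#' Write / read a dataset as PNG images plus a CSV manifest
#'
#' @param dataset a `blt_dataset`.
#' @param dir directory to write to (created if needed).
#' @return `write_dataset()` returns the manifest path invisibly;
#'   `read_dataset()` returns a `blt_dataset` (with a `NULL` config).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$labels)) {
    png::writePNG(dataset$images[, , i],
                  file.path(dir, dataset$manifest$filename[i]))
  }
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(dataset$manifest, path)
  invisible(path)
}

#' @param dir directory containing `manifest.csv` and the PNGs.
#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              col_types = readr::cols(
                                filename = readr::col_character(),
                                labels = readr::col_character(),
                                condition = readr::col_character(),
                                seed = readr::col_integer()
                              ))
  imgs <- lapply(manifest$filename, function(f) {
    m <- png::readPNG(file.path(dir, f))
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  res <- nrow(imgs[[1]])
  images <- array(unlist(imgs), c(res, res, length(imgs)))
  labels <- lapply(strsplit(manifest$labels, ";"), as.integer)
  structure(
    list(images = images, labels = labels, manifest = manifest,
         role = "unknown", config = NULL),
    class = "blt_dataset"
  )
}

#' Monte-Carlo estimate of debris coverage of target ink
#'
#' Fraction of the target digit's ink pixels that are covered by debris ink,
#' averaged over freshly sampled scenes. Coverage grows with the number of
#' fragments, which is how debris level maps onto task difficulty.
#'
#' @param config a debris [stimulus_config()].
#' @param n_scenes number of scenes to average over.
#' @return A single number in `[0, 1]`.
#' @export
debris_coverage <- function(config, n_scenes = 1000) {
  cov <- numeric(n_scenes)
  for (i in seq_len(n_scenes)) {
    s <- compose_debris(config)
    ink <- s$target_mask > 0
    cov[i] <- sum(s$debris_mask[ink]) / sum(ink)
  }
  mean(cov)
}
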