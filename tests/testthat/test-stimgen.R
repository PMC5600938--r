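test_that("rendering is translation invariant and centred glyphs are centred", {
  cfg <- stimulus_config(task = "debris", jitter_extent = 60)
  a <- render_digit(4, c(256, 256), cfg)
  b <- render_digit(4, c(276, 246), cfg)
  # b is a pure translation of a by (+20, -10) in (x, y)
  expect_equal(b[1:400, 21:450], a[11:410, 1:430])

  img <- render_digit(8, c(256, 256), cfg)
  rows <- range(which(rowSums(img) > 0))
  cols <- range(which(colSums(img) > 0))
  expect_lte(abs(mean(rows) - 256.5), 1)
  expect_lte(abs(mean(cols) - 256.5), 1)
})

test_that("glyphs have class-appropriate ink and domain checks fire", {
  cfg <- stimulus_config()
  ink <- vapply(0:9, function(cl) sum(render_digit(cl, c(256, 256), cfg)), 0)
  expect_lt(ink[1 + 1], ink[8 + 1]) # "1" uses less ink than "8"
  expect_true(all(ink > 0))
  expect_error(render_digit(10, c(256, 256), cfg), "0-9")
  expect_error(render_digit(3, c(5, 5), cfg), "jitter")
})

test_that("clutter composition records classes, positions and depth order", {
  cfg <- stimulus_config(task = "clutter", n_digits = 3, seed = 4)
  set.seed(42)
  s <- compose_clutter(cfg)
  expect_length(s$scene$targets, 3)
  expect_length(unique(s$scene$targets), 3) # pairwise distinct classes
  expect_equal(s$scene$depth_order, 1:3)
  expect_true(all(s$image %in% c(0, 1)))

  # a single digit reduces to render_digit at the sampled position
  cfg1 <- stimulus_config(task = "clutter", n_digits = 1)
  set.seed(7)
  s1 <- compose_clutter(cfg1)
  ref <- render_digit(s1$scene$targets, s1$scene$positions[1, ], cfg1)
  expect_equal(s1$image, ref)
})

test_that("later digits own overlapping pixels (depth order)", {
  # collapse the jitter region to a point so two digits coincide exactly
  cfg <- stimulus_config(task = "clutter", n_digits = 2, jitter_extent = 0)
  set.seed(11)
  s <- compose_clutter(cfg)
  second <- render_digit(s$scene$targets[2], s$scene$positions[2, ], cfg)
  overlap_ink <- s$image > 0 & second > 0
  expect_gt(sum(overlap_ink), 0)
  expect_true(all(s$visible[overlap_ink] == 2))
})

test_that("debris scenes obey the fragment model", {
  cfg0 <- stimulus_config(task = "debris", n_fragments = 0)
  set.seed(3)
  s0 <- compose_debris(cfg0)
  expect_equal(s0$image, s0$target_mask) # no fragments: unoccluded render
  expect_equal(sum(s0$debris_mask), 0)

  cfg <- stimulus_config(task = "debris", n_fragments = 10)
  set.seed(3)
  s <- compose_debris(cfg)
  expect_equal(nrow(s$scene$fragments), 10)
  expect_true(all(s$scene$fragments$class %in% 0:9))
  expect_length(s$scene$targets, 1)

  expect_error(stimulus_config(task = "debris",
                               fragment_size_range = c(100, 600)),
               "canvas")
})

test_that("area-average downsampling is exact for integer factors", {
  const <- matrix(0.37, 512, 512)
  expect_equal(downsample(const, 32), matrix(0.37, 32, 32))
  expect_equal(downsample(matrix(0, 512, 512), 32), matrix(0, 32, 32))

  # one aligned 16x16 design block maps to exactly one full-intensity pixel
  img <- matrix(0, 512, 512)
  img[17:32, 33:48] <- 1
  out <- downsample(img, 32)
  expect_equal(out[2, 3], 1)
  expect_equal(sum(out), 1)

  expect_error(downsample(matrix(0, 500, 500), 32), "integer")
})

test_that("pixel-wise normalization matches its definition", {
  # direct substitution: x = 5, mean 3, sd 2 -> 1
  stats <- structure(list(mean = matrix(3, 1, 1), sd = matrix(2, 1, 1)),
                     class = "blt_norm_stats")
  expect_equal(normalize(matrix(5, 1, 1), stats), matrix(1, 1, 1))

  cfg <- stimulus_config(task = "debris", n_fragments = 10, seed = 5)
  ds <- generate_dataset(cfg, 60, role = "train")
  st <- fit_normalization(ds)
  normed <- normalize(ds$images, st)
  refit <- fit_normalization(list(images = normed, role = "train"))
  live <- st$sd > 0
  expect_lt(max(abs(refit$mean[live])), 1e-12)
  expect_lt(max(abs(refit$sd[live] - 1)), 1e-12)
  # zero-variance positions map to zero
  expect_true(all(normed[rep(!live, dim(normed)[3])] == 0))

  # a dataset of identical images normalizes to all zeros
  same <- list(images = array(rep(ds$images[, , 1], 4), c(32, 32, 4)),
               role = "train")
  st2 <- fit_normalization(same)
  expect_equal(normalize(same$images[, , 1], st2), matrix(0, 32, 32))

  expect_error(normalize(matrix(0, 16, 16), st), "resolution")
})

test_that("gaussian noise respects sigma and domain checks", {
  img <- matrix(rnorm(64), 8, 8)
  expect_identical(add_gaussian_noise(img, 0), img)
  expect_error(add_gaussian_noise(img, -1), "non-negative")
  set.seed(1)
  noisy <- add_gaussian_noise(matrix(0, 200, 200), 2)
  expect_lt(abs(sd(noisy) - 2), 0.05)
})

test_that("dataset generation is a pure function of (config, seed, role)", {
  cfg <- stimulus_config(task = "clutter", n_digits = 3, seed = 21)
  a <- generate_dataset(cfg, 8, role = "val")
  b <- generate_dataset(cfg, 8, role = "val")
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$images, b$images)
  # split streams are independent: a different role gives different scenes
  d <- generate_dataset(cfg, 8, role = "test")
  expect_false(identical(a$images, d$images))
  # every row carries the full label set
  expect_true(all(lengths(a$labels) == 3))
  expect_true(all(vapply(a$labels, function(l) length(unique(l)), 0L) == 3))
  expect_named(a$manifest, c("filename", "labels", "condition", "seed"))
})

test_that("PNG + manifest round trip preserves the dataset", {
  cfg <- stimulus_config(task = "debris", n_fragments = 10, seed = 9)
  ds <- generate_dataset(cfg, 4, role = "test")
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$manifest$labels, ds$manifest$labels)
  expect_lt(max(abs(back$images - ds$images)), 1 / 255) # 8-bit quantization
})
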