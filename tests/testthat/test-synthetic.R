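test_that("depth of field follows the axial-resolution law", {
  expect_equal(dof(0.55, 0.5), 0.55 / (4 * (1 - sqrt(0.75))))
  expect_equal(dof(1.10, 0.5), 2 * dof(0.55, 0.5))
  # monotone divergence as NA -> 0
  nas <- c(0.5, 0.25, 0.1, 0.05)
  dz <- vapply(nas, function(a) dof(0.55, a), 0)
  expect_true(all(diff(dz) > 0))
  expect_gt(dof(0.55, 0.001), 1e5)
  expect_error(dof(0.55, 1.2), "aperture")
})

test_that("scan step is half the depth of field (Nyquist)", {
  expect_equal(step_size(0.55, 0.28), dof(0.55, 0.28) / 2)
  expect_lt(step_size(0.55, 0.28), dof(0.55, 0.28))
  op <- optics_spec()
  st <- render_stack(synthetic_scene(size = c(16, 16)), op, n_frames = 41L)
  expect_length(st, 41L)
  expect_equal(st$z_um[21], 0)
  expect_equal(diff(st$z_um)[1], op$step_um)
})

test_that("scenes are reproducible from their seed and textures differ", {
  s1 <- synthetic_scene(seed = 9)
  s2 <- synthetic_scene(seed = 9)
  expect_identical(s1$pixels, s2$pixels)
  expect_gt(stats::sd(s1$pixels), 0)
  s3 <- synthetic_scene(seed = 10)
  expect_false(identical(s1$pixels, s3$pixels))
  e <- synthetic_scene("edges", size = c(32, 32), seed = 1)
  expect_gt(stats::sd(e$pixels), 0)
})

test_that("rendering is sharp at focus, symmetric in defocus, seeded", {
  scene <- synthetic_scene(size = c(32, 32), seed = 4)
  st <- render_stack(scene, n_frames = 9L, read_noise_sd = 0, seed = 4)
  tf <- st$meta$true_focus_index
  expect_equal(st$frames[[tf]]$pixels, round(scene$pixels))
  for (k in 1:4)
    expect_equal(st$frames[[tf - k]]$pixels, st$frames[[tf + k]]$pixels)
  st2 <- render_stack(scene, n_frames = 9L, seed = 11)
  st3 <- render_stack(scene, n_frames = 9L, seed = 11)
  expect_identical(st2$frames[[1]]$pixels, st3$frames[[1]]$pixels)
  expect_false(identical(st2$frames[[1]]$pixels,
                         render_stack(scene, n_frames = 9L, seed = 12)$frames[[1]]$pixels))
})

test_that("gradient measures recover the true focus on a clean rendered stack", {
  st <- small_test_stack(seed = 13L, n_frames = 21L)
  tf <- st$meta$true_focus_index
  for (id in c("TEN1", "BRE", "BOD", "EIG")) {
    cv <- fm_curves(st, id)[[id]]
    expect_lte(abs(which.max(cv$values) - tf), 1L)
  }
})

test_that("added Poisson noise has the requested mean and is seed-stable", {
  scene <- synthetic_scene(size = c(96, 96), seed = 2, offset = 500)
  st <- render_stack(scene, n_frames = 5L, seed = 2)
  for (level in c(10, 100)) {
    noisy <- add_poisson_noise(st, level, seed = 3)
    added <- unlist(lapply(1:5, function(i)
      noisy$frames[[i]]$pixels - st$frames[[i]]$pixels))
    expect_lt(abs(mean(added) - level) / level, 0.01)   # ~46k samples
    expect_gt(stats::var(added), 0.8 * level)
    again <- add_poisson_noise(st, level, seed = 3)
    expect_identical(noisy$frames[[2]]$pixels, again$frames[[2]]$pixels)
  }
  scaled <- add_poisson_noise(st, 25, seed = 1, mode = "scaled")
  expect_false(identical(scaled$frames[[1]]$pixels, st$frames[[1]]$pixels))
})

test_that("the quadratic illumination ramp peaks at the first row and preserves histogram invariances", {
  st <- small_test_stack(seed = 6L, n_frames = 5L)
  sh <- apply_illumination_gradient(st, peak = 1.0)
  f0 <- st$frames[[3]]$pixels
  f1 <- sh$frames[[3]]$pixels
  expect_equal(f1[1, ], f0[1, ])                       # vertex row unchanged
  expect_equal(f1[nrow(f1), ], 0 * f0[nrow(f0), ])     # opposite edge -> 0
  H <- nrow(f0)
  mid <- (H / 2)
  expect_equal(f1[mid, ], f0[mid, ] * (1 - ((mid - 1) / (H - 1))^2))
  expect_false(isTRUE(all.equal(fm_entropy(image_frame(round(f1), 12L)),
                                fm_entropy(st$frames[[3]]))))
  # histogram permutation invariance still holds on the shaded frame
  g <- round(f1)
  p <- matrix(sample(as.numeric(g)), nrow(g), ncol(g))
  expect_equal(fm_entropy(p), fm_entropy(g))
})

test_that("a moderate illumination ramp moves the TEN1 peak by at most one step", {
  st <- small_test_stack(seed = 21L, n_frames = 21L)
  sh <- apply_illumination_gradient(st, peak = 0.8)
  p0 <- which.max(fm_curves(st, "TEN1")$TEN1$values)
  p1 <- which.max(fm_curves(sh, "TEN1")$TEN1$values)
  expect_lte(abs(p1 - p0), 1L)
})

test_that("seeded generators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(synthetic_scene(size = c(16, 16), seed = 5))
  invisible(render_stack(synthetic_scene(size = c(16, 16), seed = 5),
                         n_frames = 3L, seed = 5))
  b <- rnorm(1)
  expect_identical(a, b)
})
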