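make_stack <- function(n = 5L, H = 8L, W = 6L, seed = 1L, dark = FALSE) {
  set.seed(seed)
  frames <- lapply(seq_len(n), function(i)
    image_frame(matrix(sample.int(4000L, H * W, replace = TRUE), H, W),
                bit_depth = 12L, axes = "spatial_spectral"))
  dk <- if (dark)
    image_frame(matrix(sample.int(50L, H * W, replace = TRUE), H, W),
                bit_depth = 12L, axes = "spatial_spectral")
  focus_stack(frames, z_um = seq_len(n) * 1.5, dark_frame = dk)
}

test_that("write/read round-trips pixels and z positions in both formats", {
  st <- make_stack(dark = TRUE)
  for (ext in c("envi", "tiff")) {
    path <- file.path(tempdir(), paste0("rt_", ext,
                                        if (ext == "envi") ".raw" else ".tif"))
    write_stack(st, path, format = ext)
    back <- read_stack(path)
    expect_length(back, 5L)
    for (i in 1:5)
      expect_equal(back$frames[[i]]$pixels, st$frames[[i]]$pixels)
    expect_equal(back$z_um, st$z_um)
    expect_equal(back$dark_frame$pixels, st$dark_frame$pixels)
    expect_identical(back$frames[[1]]$axes, "spatial_spectral")
  }
})

test_that("an 80-frame synthetic ENVI stack survives the raw format", {
  scene <- synthetic_scene(size = c(16L, 16L), seed = 5)
  st <- render_stack(scene, n_frames = 80L, seed = 5)
  path <- file.path(tempdir(), "hsi80.raw")
  write_stack(st, path)
  back <- read_stack(path)
  expect_length(back, 80L)
  expect_identical(
    do.call(rbind, lapply(back$frames, `[[`, "pixels")),
    do.call(rbind, lapply(st$frames, `[[`, "pixels")))
})

test_that("directory stacks are reordered by the manifest z positions", {
  st <- make_stack(n = 4L)
  d <- file.path(tempdir(), "dirstack")
  dir.create(d, showWarnings = FALSE)
  # write frames under shuffled names, manifest pairs each with its z
  shuffle <- c(3L, 1L, 4L, 2L)
  files <- sprintf("frame_%s.tif", letters[seq_along(shuffle)])
  for (i in seq_along(shuffle)) {
    one <- focus_stack(st$frames[shuffle[i]], st$z_um[shuffle[i]])
    write_stack(one, file.path(d, files[i]), format = "tiff")
  }
  jsonlite::write_json(list(files = files, z_um = st$z_um[shuffle],
                            bit_depth = 12L, axes = "spatial_spectral"),
                       file.path(d, "manifest.json"), auto_unbox = TRUE)
  back <- read_stack(d)
  expect_equal(back$z_um, st$z_um)
  for (i in 1:4)
    expect_equal(back$frames[[i]]$pixels, st$frames[[i]]$pixels)
})

test_that("loading errors are distinct and informative", {
  path <- file.path(tempdir(), "broken.raw")
  writeBin(raw(10), path)
  expect_error(read_stack(path), "manifest")
  st <- make_stack(n = 3L)
  write_stack(st, path)
  file.remove(sub("\\.raw$", ".hdr", path))
  expect_error(read_stack(path), "header")
})

test_that("dark subtraction clamps at zero and clears the dark frame", {
  f100 <- matrix(100, 4, 4)
  st <- focus_stack(list(f100), 0, dark_frame = f100)
  expect_equal(subtract_dark(st)$frames[[1]]$pixels, matrix(0, 4, 4))

  st2 <- focus_stack(list(matrix(50, 4, 4)), 0, dark_frame = f100)
  expect_equal(subtract_dark(st2)$frames[[1]]$pixels, matrix(0, 4, 4))

  fr <- rbind(c(5, 7, 9), c(9, 11, 13), c(6, 8, 10))
  dk <- rbind(c(1, 2, 3), c(3, 4, 5), c(2, 3, 4))
  st3 <- focus_stack(list(fr), 0, dark_frame = dk)
  out <- subtract_dark(st3)
  expect_equal(out$frames[[1]]$pixels, fr - dk)
  expect_null(out$dark_frame)
  expect_true(all(out$frames[[1]]$pixels >= 0))

  expect_warning(subtract_dark(make_stack(n = 2L)), "no dark frame")
})

test_that("ROI cropping is identical across frames and validates bounds", {
  st <- make_stack(n = 3L, H = 10L, W = 10L)
  full <- crop_roi(st, roi_spec(0, 0, 10, 10))
  expect_equal(full$frames[[2]]$pixels, st$frames[[2]]$pixels)

  small <- crop_roi(st, roi_spec(2, 3, 5, 4))
  expect_equal(dim(small$frames[[1]]$pixels), c(5L, 4L))
  expect_length(small, 3L)
  expect_equal(small$z_um, st$z_um)
  expect_equal(small$frames[[3]]$pixels, st$frames[[3]]$pixels[3:7, 4:7])

  expect_error(crop_roi(st, roi_spec(0, 7, 5, 4)), "outside")
})

test_that("focus measures are unchanged by a full-frame ROI crop", {
  st <- make_stack(n = 1L, H = 12L, W = 12L)
  cropped <- crop_roi(st, roi_spec(0, 0, 12, 12))
  a <- compute_all_fms(st$frames[[1]])
  b <- compute_all_fms(cropped$frames[[1]])
  expect_equal(a$value, b$value)
})
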