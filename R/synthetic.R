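# Synthetic through-focus stacks with known ground truth.  The generator
# emulates what matters for focus-measure evaluation: a textured in-focus
# scene, blur growing symmetrically with defocus distance (Gaussian PSF,
# sigma linear in |z - z_focus|), detector read noise and integer
# quantization, plus the two robustness protocols (additive Poisson noise
# and a multiplicative quadratic illumination gradient).

#' Depth of field of a microscope objective
#'
#' `dz = lambda / (4 * n * (1 - sqrt(1 - (NA/n)^2)))` -- the axial range
#' over which the image stays acceptably sharp.
#'
#' @param wavelength_um effective illumination wavelength in micrometres.
#' @param na numerical aperture of the objective (0 < NA < n).
#' @param n refractive index of the immersion medium (air = 1).
#' @return depth of field in micrometres.
#' @export
dof <- function(wavelength_um, na, n = 1) {
  stopifnot(wavelength_um > 0, na > 0)
  if (na >= n) stop("numerical aperture must be smaller than the refractive index",
                    call. = FALSE)
  wavelength_um / (4 * n * (1 - sqrt(1 - (na / n)^2)))
}

#' Through-focus sampling step from the Nyquist criterion
#'
#' Half the depth of field, so the focus curve is sampled at twice the
#' axial resolution.
#'
#' @inheritParams dof
#' @return step size in micrometres.
#' @export
step_size <- function(wavelength_um, na, n = 1) dof(wavelength_um, na, n) / 2

#' Optics specification for the synthetic imager
#'
#' @inheritParams dof
#' @param blur_gain_px_per_um Gaussian PSF sigma, in pixels, per
#'   micrometre of defocus.
#' @return list of class `optics_spec` with the derived `dof_um` and
#'   `step_um`.
#' @export
optics_spec <- function(wavelength_um = 0.55, na = 0.28, n = 1,
                        blur_gain_px_per_um = 0.29) {
  dz <- dof(wavelength_um, na, n)
  structure(list(wavelength_um = wavelength_um, na = na, n = n,
                 blur_gain_px_per_um = blur_gain_px_per_um,
                 dof_um = dz, step_um = dz / 2),
            class = "optics_spec")
}

# Band-pass filtered periodic 1D profile, unit sd: white noise whose
# Fourier support is restricted to wavelengths in [lo, hi] pixels.
bandpass_profile <- function(n, lo, hi) {
  z <- stats::rnorm(n)
  fz <- stats::fft(z)
  f <- abs(fft_freqs(n))
  fz[f < 1 / hi | f > 1 / lo] <- 0
  p <- Re(stats::fft(fz, inverse = TRUE)) / n
  p / stats::sd(p)
}

#' Synthetic in-focus scene
#'
#' Three textures are available.  `"soil_like"` is a rank-8 mixture of
#' outer products of band-pass-filtered 1D profiles (granule scale 3-10
#' px, geometrically decaying weights): the separable structure mimics a
#' pushbroom frame of a granular sample, where the image is approximately
#' (spatial abundance profile) x (spectral signature), and its low rank
#' is what makes the PCA component count flat in the absence of blur and
#' noise.  `"edges"` is a periodic bar target; `"mixed"` averages the
#' two.  Intensities are `offset + amplitude * texture` counts (texture
#' has unit sd), clamped to the sensor range.
#'
#' @param texture `"soil_like"`, `"edges"` or `"mixed"`.
#' @param size `c(H, W)` in pixels (even values; default 96 x 96).
#' @param offset,amplitude baseline counts and texture standard
#'   deviation, in detector counts.
#' @param bit_depth sensor bit depth.
#' @param axes axis semantics of the rendered frames.
#' @param seed integer seed; the scene is reproducible from it.
#' @return an [image_frame] (continuous-valued; quantization happens at
#'   render time).
#' @export
synthetic_scene <- function(texture = c("soil_like", "edges", "mixed"),
                            size = c(96L, 96L), offset = 300, amplitude = 200,
                            bit_depth = 12L,
                            axes = "spatial_spectral", seed = 1L) {
  texture <- match.arg(texture)
  H <- size[1L]; W <- size[2L]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  soil <- function() {
    S <- matrix(0, H, W)
    for (q in 1:8)
      S <- S + 0.75^(q - 1) * outer(bandpass_profile(H, 3, 10),
                                    bandpass_profile(W, 3, 10))
    S / stats::sd(S)
  }
  bars <- function() {
    period <- 8
    b <- outer(sign(sin(2 * pi * seq_len(H) / period)), rep(1, W))
    b / stats::sd(b)
  }
  S <- switch(texture, soil_like = soil(), edges = bars(),
              mixed = (soil() + bars()) / sqrt(2))
  pix <- pmin(pmax(offset + amplitude * S, 0), 2^bit_depth - 1)
  image_frame(pix, bit_depth = bit_depth, axes = axes)
}

# Save/restore the RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render a through-focus stack from a scene
#'
#' The frame at focal position z is the scene blurred by a Gaussian PSF
#' with `sigma = blur_gain * |z - true_focus_z|` (sigma = 0 at true
#' focus), plus Gaussian read noise, rounded to integer counts and
#' clamped to the sensor range.  Two presets set the read noise:
#' `"hsi"` (sd 20 counts, a weak-signal NIR detector at SNR ~ 10 --
#' the regime in which the PCA reference operates) and `"video"`
#' (sd 2 counts, a well-exposed visible-range imager).  The true focus
#' index and all generator parameters are recorded in `$meta`.
#'
#' @param scene an [image_frame] from [synthetic_scene()].
#' @param optics an [optics_spec].
#' @param n_frames number of focal positions (odd recommended).
#' @param true_focus_index index of the sharp frame (default: centre).
#' @param preset `"hsi"` or `"video"`, or set `read_noise_sd` directly.
#' @param read_noise_sd detector read-noise sd in counts (overrides the
#'   preset when given).
#' @param seed integer seed for the noise stream.
#' @return a [focus_stack] with `meta$true_focus_index` set.
#' @export
render_stack <- function(scene, optics = optics_spec(), n_frames = 81L,
                         true_focus_index = (n_frames + 1L) %/% 2L,
                         preset = c("hsi", "video"),
                         read_noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(scene, "image_frame"), n_frames >= 3L)
  preset <- match.arg(preset)
  if (is.null(read_noise_sd))
    read_noise_sd <- switch(preset, hsi = 20, video = 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  top <- 2^scene$bit_depth - 1
  z <- (seq_len(n_frames) - true_focus_index) * optics$step_um
  frames <- lapply(seq_len(n_frames), function(k) {
    sigma <- optics$blur_gain_px_per_um * abs(z[k])
    p <- gaussian_blur_periodic(scene$pixels, sigma)
    if (read_noise_sd > 0)
      p <- p + stats::rnorm(length(p), 0, read_noise_sd)
    p <- pmin(pmax(round(p), 0), top)
    image_frame(p, bit_depth = scene$bit_depth, axes = scene$axes)
  })
  focus_stack(frames, z,
              meta = list(true_focus_index = true_focus_index,
                          preset = preset, read_noise_sd = read_noise_sd,
                          seed = seed, optics = unclass(optics)))
}

#' Add Poisson noise to every frame of a stack
#'
#' `mode = "additive"` (the default, matching the reference protocol)
#' draws an independent Poisson variate with mean `level` per pixel and
#' adds it to the image; `mode = "scaled"` instead replaces each pixel by
#' a Poisson draw with its own value as the rate, scaled so the added
#' variance matches `level` (signal-dependent shot noise).
#'
#' @param stack a [focus_stack].
#' @param level Poisson rate parameter (the protocol uses 10, 25, 50,
#'   100).
#' @param seed integer seed.
#' @param mode `"additive"` or `"scaled"`.
#' @return the noisy [focus_stack]; counts stay clamped to the sensor
#'   range.
#' @export
add_poisson_noise <- function(stack, level, seed = 1L,
                              mode = c("additive", "scaled")) {
  stopifnot(inherits(stack, "focus_stack"), level > 0)
  mode <- match.arg(mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  top <- 2^stack$frames[[1L]]$bit_depth - 1
  frames <- lapply(stack$frames, function(f) {
    p <- f$pixels
    p <- if (mode == "additive") p + stats::rpois(length(p), level)
    else {
      scale <- level / pmax(p, 1)
      stats::rpois(length(p), p * scale) / scale
    }
    f$pixels <- pmin(pmax(p, 0), top)
    f
  })
  meta <- stack$meta
  meta$poisson_level <- level
  focus_stack(frames, stack$z_um, dark_frame = stack$dark_frame, meta = meta)
}

#' Apply a quadratic illumination gradient to a stack
#'
#' Multiplies every frame by a fixed gray-level ramp `g`, a quadratic
#' polynomial along the spatial (row) axis with its vertex (maximum
#' value `peak`) at the first row, falling to 0 at the last:
#' `g(i) = peak * (1 - ((i - 1) / (H - 1))^2)`.
#'
#' @param stack a [focus_stack].
#' @param peak maximum of the ramp, in (0, 1] (the protocol uses 0.8,
#'   0.9 and 1.0).
#' @param axis ramp axis (1 = rows, the spatial axis; 2 = columns).
#' @return the shaded [focus_stack].
#' @export
apply_illumination_gradient <- function(stack, peak = 1.0, axis = 1L) {
  stopifnot(inherits(stack, "focus_stack"), peak > 0, peak <= 1)
  d <- dim(stack$frames[[1L]]$pixels)
  n <- d[axis]
  ramp <- peak * (1 - ((seq_len(n) - 1) / (n - 1))^2)
  G <- if (axis == 1L) matrix(ramp, d[1], d[2]) else
    matrix(ramp, d[1], d[2], byrow = TRUE)
  frames <- lapply(stack$frames, function(f) {
    f$pixels <- f$pixels * G
    f
  })
  meta <- stack$meta
  meta$illumination_peak <- peak
  focus_stack(frames, stack$z_um, dark_frame = stack$dark_frame, meta = meta)
}
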