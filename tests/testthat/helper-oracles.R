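# Naive double-loop reference implementations of the convolution and
# difference focus measures.  Deliberately slow and index-by-index so
# they stay independent of the vectorized package code they check.

random_int_frame <- function(seed, H = 8L, W = 8L, max_val = 255L) {
  set.seed(seed)
  matrix(sample.int(max_val + 1L, H * W, replace = TRUE) - 1L, H, W)
}

naive_corr_valid <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  out <- matrix(0, H - kh + 1L, W - kw + 1L)
  for (i in seq_len(H - kh + 1L)) {
    for (j in seq_len(W - kw + 1L)) {
      acc <- 0
      for (a in seq_len(kh)) for (b in seq_len(kw))
        acc <- acc + kernel[a, b] * img[i + a - 1L, j + b - 1L]
      out[i, j] <- acc
    }
  }
  out
}

naive_tenengrad <- function(img, a, theta = 0) {
  k1 <- rbind(c(-1, 0, 1), c(-a, 0, a), c(-1, 0, 1))
  gx <- naive_corr_valid(img, k1)
  gy <- naive_corr_valid(img, t(k1))
  total <- 0
  for (i in seq_len(nrow(gx))) for (j in seq_len(ncol(gx))) {
    g2 <- gx[i, j]^2 + gy[i, j]^2
    if (sqrt(g2) > theta) total <- total + g2
  }
  total
}

naive_laplacian <- function(img, variant) {
  H <- nrow(img); W <- ncol(img)
  lx <- naive_corr_valid(img, matrix(c(-1, 2, -1), 1L))
  ly <- naive_corr_valid(img, matrix(c(-1, 2, -1), 3L))
  total <- 0
  for (i in 2:(H - 1L)) for (j in 2:(W - 1L)) {
    rx <- lx[i, j - 1L]       # lx keeps all rows, loses one column margin
    ry <- ly[i - 1L, j]
    total <- total + if (variant == "EOL") (rx + ry)^2 else abs(rx) + abs(ry)
  }
  if (variant == "DLF") {
    d1 <- matrix(c(0, 0, 1, 0, -2, 0, 1, 0, 0), 3L, byrow = TRUE) / sqrt(2)
    d2 <- matrix(c(1, 0, 0, 0, -2, 0, 0, 0, 1), 3L, byrow = TRUE) / sqrt(2)
    for (m in list(d1, d2)) {
      r <- naive_corr_valid(img, m)
      total <- total + sum(abs(r))
    }
  }
  total
}

naive_derivative <- function(img, k, p, theta = 0) {
  H <- nrow(img); W <- ncol(img)
  total <- 0
  for (i in seq_len(H - k)) for (j in seq_len(W)) {
    d <- abs(img[i, j] - img[i + k, j])
    if (d > theta) total <- total + d^p
  }
  total
}

naive_eig <- function(img) {
  H <- nrow(img); W <- ncol(img)
  total <- 0
  for (i in seq_len(H - 1L)) for (j in seq_len(W))
    total <- total + (img[i + 1L, j] - img[i, j])^2
  for (i in seq_len(H)) for (j in seq_len(W - 1L))
    total <- total + (img[i, j + 1L] - img[i, j])^2
  total
}

naive_bod <- function(img) {
  H <- nrow(img); W <- ncol(img)
  total <- 0
  for (i in 2:(H - 1L)) for (j in seq_len(W))
    total <- total + (img[i + 1L, j] - img[i - 1L, j])^2
  total
}

naive_acf <- function(img) {
  H <- nrow(img); W <- ncol(img)
  s1 <- 0; s2 <- 0
  for (i in seq_len(H - 1L)) for (j in seq_len(W))
    s1 <- s1 + img[i, j] * img[i + 1L, j]
  for (i in seq_len(H - 2L)) for (j in seq_len(W))
    s2 <- s2 + img[i, j] * img[i + 2L, j]
  s1 - s2
}

naive_vol5 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  s1 <- 0
  for (i in seq_len(H - 1L)) for (j in seq_len(W))
    s1 <- s1 + img[i, j] * img[i + 1L, j]
  s1 - H * W * mean(img)^2
}

naive_mfdct <- function(img) {
  op <- matrix(c(1, 1, -1, -1, 1, 1, -1, -1,
                 -1, -1, 1, 1, -1, -1, 1, 1), 4L, 4L, byrow = TRUE)
  sum(naive_corr_valid(img, op)^2)
}

# Pairs of package implementation and oracle, used by both the unit and
# the acceptance oracle-equivalence tests.
oracle_fm_pairs <- function() {
  list(
    TEN1 = list(pkg = function(m) fm_tenengrad(m, a = 2),
                ora = function(m) naive_tenengrad(m, 2)),
    TEN2 = list(pkg = function(m) fm_tenengrad(m, a = 1),
                ora = function(m) naive_tenengrad(m, 1)),
    EOL = list(pkg = function(m) fm_laplacian_energy(m, "EOL"),
               ora = function(m) naive_laplacian(m, "EOL")),
    SML = list(pkg = function(m) fm_laplacian_energy(m, "SML"),
               ora = function(m) naive_laplacian(m, "SML")),
    DLF = list(pkg = function(m) fm_laplacian_energy(m, "DLF"),
               ora = function(m) naive_laplacian(m, "DLF")),
    ABG = list(pkg = function(m) fm_derivative(m, 1L, 1),
               ora = function(m) naive_derivative(m, 1L, 1)),
    SAG = list(pkg = function(m) fm_derivative(m, 1L, 2),
               ora = function(m) naive_derivative(m, 1L, 2)),
    BRE = list(pkg = function(m) fm_derivative(m, 2L, 2),
               ora = function(m) naive_derivative(m, 2L, 2)),
    EIG = list(pkg = fm_energy_of_gradient, ora = naive_eig),
    BOD = list(pkg = fm_boddeke, ora = naive_bod),
    ACF = list(pkg = fm_vollath_f4, ora = naive_acf),
    VOL5 = list(pkg = fm_vollath_f5, ora = naive_vol5),
    MFDCT = list(pkg = fm_midfreq_dct, ora = naive_mfdct))
}

# Small rendered stack shared by pipeline-level unit tests.
small_test_stack <- function(seed = 7L, n_frames = 31L, preset = "hsi") {
  scene <- synthetic_scene(size = c(64L, 64L), seed = seed)
  render_stack(scene, n_frames = n_frames, preset = preset, seed = seed)
}
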