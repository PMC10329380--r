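# Shared fixtures: small deterministic stacks and independently-coded
# oracles used across test files.

# random integer stack as an ImageStack
random_stack <- function(t = 10L, h = 32L, w = 32L, seed = 1L,
                         dt = 0.15, px = 0.1) {
  set.seed(seed)
  arr <- array(sample.int(65535L, t * h * w, replace = TRUE) - 1L, c(h, w, t))
  image_stack(arr, dt, px)
}

# a noiseless stack containing given particles: list of
# list(x=, y=, birth=, death=, photons=) rendered as pixel-integrated
# Gaussians on a constant background, no noise
noiseless_stack <- function(particles, t = 20L, h = 48L, w = 48L,
                            sigma = 1.0, background = 0, dt = 0.15) {
  arr <- array(background, c(h, w, t))
  for (pt in particles) {
    for (fr in pt$birth:pt$death) {
      fx <- pnorm((0:(w - 1) + 0.5 - pt$x) / sigma) -
        pnorm((0:(w - 1) - 0.5 - pt$x) / sigma)
      fy <- pnorm((0:(h - 1) + 0.5 - pt$y) / sigma) -
        pnorm((0:(h - 1) - 0.5 - pt$y) / sigma)
      arr[, , fr + 1] <- arr[, , fr + 1] + pt$photons * outer(fy, fx)
    }
  }
  image_stack(arr, dt, 0.1)
}

# Independent brute-force kymograph: plain nested loops and its own scalar
# bilinear interpolation, deliberately sharing no code with the package.
brute_force_kymograph <- function(stack, x0, y0, x1, y1, linewidth,
                                  reduction) {
  interp <- function(img, x, y) {
    i0 <- min(floor(x), ncol(img) - 2); j0 <- min(floor(y), nrow(img) - 2)
    fx <- x - i0; fy <- y - j0
    img[j0 + 1, i0 + 1] * (1 - fx) * (1 - fy) +
      img[j0 + 1, i0 + 2] * fx * (1 - fy) +
      img[j0 + 2, i0 + 1] * (1 - fx) * fy +
      img[j0 + 2, i0 + 2] * fx * fy
  }
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ux <- (x1 - x0) / len; uy <- (y1 - y0) / len
  L <- floor(len) + 1
  Tn <- dim(stack$pixels)[3]
  K <- matrix(0, Tn, L)
  half <- (linewidth - 1) / 2
  for (t in seq_len(Tn)) {
    img <- stack$pixels[, , t]
    for (j in seq_len(L)) {
      px <- x0 + (j - 1) * ux; py <- y0 + (j - 1) * uy
      vals <- numeric(linewidth)
      for (k in seq_len(linewidth)) {
        o <- k - 1 - half
        vals[k] <- interp(img, px + o * (-uy), py + o * ux)
      }
      K[t, j] <- if (reduction == "max") max(vals) else mean(vals)
    }
  }
  K
}

# apply the camera noise model to an expected-photon stack:
# Poisson(signal + background) + Gaussian read noise, clamped at 0
camera_noise <- function(stack, background = 20, read_sd = 2, seed = 1L) {
  set.seed(seed)
  lam <- stack$pixels + background
  counts <- array(rpois(length(lam), lam), dim(lam)) +
    round(rnorm(length(lam), 0, read_sd))
  counts[counts < 0] <- 0
  storage.mode(counts) <- "integer"
  image_stack(counts, stack$frame_interval_s, stack$pixel_size_um)
}

# textbook two-sample t statistics (direct formulas)
welch_t_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  (mean(a) - mean(b)) / sqrt(va + vb)
}
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# shift an image by (dx, dy) via the Fourier shift theorem (periodic)
fourier_shift <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  ky <- c(0:(ceiling(h / 2) - 1), -(floor(h / 2)):-1)
  kx <- c(0:(ceiling(w / 2) - 1), -(floor(w / 2)):-1)
  ph <- exp(-2i * pi * (outer(ky, rep(1, w)) * dy / h +
                          outer(rep(1, h), kx) * dx / w))
  Re(fft(fft(img) * ph, inverse = TRUE)) / (h * w)
}
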