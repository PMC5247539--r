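# Brute-force oracles and small fixture builders, independent of the
# package's vectorised implementations.

# plain per-pixel IPA loop (strict inequality, valid pixels only)
brute_ipa <- function(values, x) {
  n_above <- 0L
  n_total <- 0L
  for (v in as.vector(values)) {
    if (is.finite(v)) {
      n_total <- n_total + 1L
      if (v > x) n_above <- n_above + 1L
    }
  }
  1000 * n_above / n_total
}

# per-column max over the explicit lumen..iel (or fallback) span
brute_enface <- function(mu, lumen, iel, valid, axial_pitch, fallback_mm) {
  nf <- dim(mu)[1]; na <- dim(mu)[2]; ns <- dim(mu)[3]
  out <- matrix(NA_real_, nf, na)
  for (f in seq_len(nf)) {
    for (a in seq_len(na)) {
      if (!valid[f, a]) next
      lo <- floor(lumen[f, a])
      hi <- if (is.na(iel[f, a])) ceiling(lo + fallback_mm / axial_pitch)
            else ceiling(iel[f, a])
      hi <- min(hi, ns - 1)
      if (lo > hi) next
      best <- NA_real_
      for (s in lo:hi) {
        v <- mu[f, a, s + 1]
        if (is.finite(v) && (!is.finite(best) || v > best)) best <- v
      }
      out[f, a] <- best
    }
  }
  out
}

# single-scattering A-line on a radial grid, optionally with system optics
decay_intensity <- function(mu, r, i0 = 1, system = NULL) {
  ts <- if (is.null(system)) 1 else compensation_curve(system, r)
  ts * i0 * exp(-mu * r)
}

# small pullback with one homogeneous A-line per (frame, aline)
flat_pullback <- function(mu = 3, nf = 1L, na_ = 4L, ns = 80L,
                          axial_pitch = 0.01, lumen_idx = 10L, i0 = 100,
                          noise_floor = 0) {
  geom <- oct_geometry(axial_pitch = axial_pitch, n_alines = na_,
                       frame_pitch = 0.2, catheter_offset = 0.5)
  r <- radial_distance(geom, 0:(ns - 1L))
  r_lum <- r[lumen_idx + 1L]
  line <- c(rep(noise_floor, lumen_idx),
            i0 * exp(-mu * (r[(lumen_idx + 1L):ns] - r_lum)))
  intensity <- array(0, dim = c(nf, na_, ns))
  for (f in seq_len(nf)) for (a in seq_len(na_)) intensity[f, a, ] <- line
  pb <- oct_pullback(intensity, geom, noise_floor = noise_floor)
  ct <- wall_contours(lumen = matrix(lumen_idx, nf, na_),
                      iel = matrix(ns - 5, nf, na_),
                      valid = matrix(TRUE, nf, na_), n_samples = ns)
  list(pullback = pb, contours = ct, geom = geom)
}

float32 <- function(x) octipa:::float32_snap(x)
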