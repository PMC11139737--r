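#' Mono-exponential tail rate from the last two time points
#'
#' `k = log(A6 / A7) / (t7 - t6)` when the curve is genuinely falling
#' (`A6 > A7 > 0`). Rising, flat or empty voxels fall back to the physical
#' decay constant: after decay-uncorrection nothing can decay slower than
#' physics allows, and a fitted `k <= 0` would make the tail integral
#' diverge. The function is total by design; callers count fallbacks as a
#' QC metric.
#'
#' @param A6,A7 Physical activities at the last two time points
#'   (vectors allowed).
#' @param t6,t7 The corresponding times (s), `t7 > t6`.
#' @param lambda_phys Physical decay constant (s^-1).
#' @return Tail rate(s) (s^-1), with attribute `fallback` (logical vector).
#' @export
tail_rate <- function(A6, A7, t6, t7, lambda_phys) {
  if (t7 <= t6) stop("t7 must be greater than t6", call. = FALSE)
  ok <- is.finite(A6) & is.finite(A7) & A6 > A7 & A7 > 0
  k <- rep(lambda_phys, length(A7))
  k[ok] <- log(A6[ok] / A7[ok]) / (t7 - t6)
  attr(k, "fallback") <- !ok
  k
}

#' Trapezoid-plus-tail time integral of a sampled physical curve
#'
#' The integral from 0 to infinity of a physically decaying activity
#' sampled at the frame midpoints: trapezoid between the first and last
#' midpoint, a left-edge piece from injection (t = 0) to the first
#' midpoint, and a mono-exponential tail `A_last / k` beyond the last
#' midpoint with `k` from [tail_rate()].
#'
#' Left-edge options: `"triangle"` (linear ramp from 0 at injection to
#' the first value — the physical default, activity is zero before the
#' bolus arrives), `"rectangle"` (first value held constant back to 0,
#' appropriate when the signal is already at speed in the first frame),
#' or `"none"`.
#'
#' @param t Sample times (s), strictly increasing, first > 0.
#' @param y Physical activity values at `t` (same length).
#' @param lambda_phys Physical decay constant (s^-1), tail fallback rate.
#' @param left_edge One of "triangle", "rectangle", "none".
#' @return The integral in units of `y` times seconds; attribute
#'   `tail_fallback` says whether the tail rate fell back to physics.
#' @export
trapezoid_tail_integral <- function(t, y, lambda_phys,
                                    left_edge = c("triangle", "rectangle", "none")) {
  left_edge <- match.arg(left_edge)
  stopifnot(length(t) == length(y))
  if (length(t) < 2L) {
    stop("at least two time points are required", call. = FALSE)
  }
  n <- length(t)
  core <- sum(diff(t) * (y[-1] + y[-n]) / 2)
  edge <- switch(left_edge,
                 triangle = t[1] * y[1] / 2,
                 rectangle = t[1] * y[1],
                 none = 0)
  k <- tail_rate(y[n - 1], y[n], t[n - 1], t[n], lambda_phys)
  tail <- if (y[n] > 0) y[n] / as.numeric(k) else 0
  out <- core + edge + tail
  attr(out, "tail_fallback") <- attr(k, "fallback")
  out
}

#' Voxel-wise time-integrated activity map
#'
#' Per voxel: the decay correction is removed at the frame midpoints
#' (restoring physical activity), then the trapezoid-plus-tail integral is
#' taken and converted to MBq h per voxel, normalized per MBq injected.
#' The trapezoid runs on physical values because cumulated activity is an
#' integral of the physically decaying signal.
#'
#' @param image A decay-corrected `dynamic_image`.
#' @param nuclide A [nuclide_spec()] (or `lambda` directly).
#' @param injected_MBq Injected activity (MBq, > 0).
#' @param lambda Physical decay constant; overrides `nuclide`.
#' @param left_edge Left-edge rule, see [trapezoid_tail_integral()].
#' @return A `tia_map`: list with 3-D `voxels` (MBq h/MBq per voxel),
#'   `voxel_size_mm`, and QC fields `tail_fallback_fraction`,
#'   `left_edge`.
#' @export
voxel_tia_map <- function(image, nuclide = NULL, injected_MBq,
                          lambda = NULL,
                          left_edge = c("triangle", "rectangle", "none")) {
  left_edge <- match.arg(left_edge)
  stopifnot(inherits(image, "dynamic_image"), injected_MBq > 0)
  if (!image$decay_corrected) {
    stop("expected a decay-corrected dynamic image", call. = FALSE)
  }
  if (is.null(lambda)) {
    stopifnot(inherits(nuclide, "nuclide_spec"))
    lambda <- decay_constant(nuclide)
  }
  sched <- image$schedule
  nf <- n_frames(sched)
  if (nf < 2L) stop("at least two frames are required", call. = FALSE)
  dims <- dim(image$voxels)[1:3]
  nvox <- prod(dims)
  V <- matrix(image$voxels, nrow = nvox, ncol = nf)
  tmid <- sched$mid_s
  # physical activity at midpoints
  V <- sweep(V, 2, exp(-lambda * (tmid - reference_time(sched))), `*`)

  dt <- diff(tmid)
  core <- as.vector((V[, -nf, drop = FALSE] + V[, -1, drop = FALSE]) %*%
                      (dt / 2))
  edge <- switch(left_edge,
                 triangle = tmid[1] * V[, 1] / 2,
                 rectangle = tmid[1] * V[, 1],
                 none = 0)
  k <- tail_rate(V[, nf - 1], V[, nf], tmid[nf - 1], tmid[nf], lambda)
  tail <- ifelse(V[, nf] > 0, V[, nf] / as.numeric(k), 0)
  integral <- core + edge + tail  # kBq s / mL

  voxel_mL <- (image$voxel_size_mm / 10)^3
  tia <- seconds_to_hours(integral * voxel_mL / 1000) / injected_MBq
  tia[tia < 0] <- 0
  # QC: fitted-tail failures among voxels that actually have a tail
  has_tail <- V[, nf] > 0
  fb <- if (any(has_tail)) mean(attr(k, "fallback")[has_tail]) else 0
  structure(list(voxels = array(tia, dim = dims),
                 voxel_size_mm = image$voxel_size_mm,
                 tail_fallback_fraction = fb,
                 left_edge = left_edge),
            class = "tia_map")
}

#' @export
print.tia_map <- function(x, ...) {
  cat(sprintf("<tia_map> %s voxels at %g mm; tail fallback %.1f%%, left edge '%s'\n",
              paste(dim(x$voxels), collapse = "x"), x$voxel_size_mm,
              100 * x$tail_fallback_fraction, x$left_edge))
  invisible(x)
}

# micro-Gy per MBq injected, from TIA (MBq h/MBq per voxel):
# decays = TIA * 3600 s/h * 1e6 decays/(MBq s); energy = decays * E_MeV *
# 1.602e-13 J/MeV; dose = energy / voxel mass (kg); reported as uGy.
MeV_to_J <- 1.602e-13

dose_scale_uGy <- function(energy_MeV_per_decay, voxel_mL, density_g_per_mL) {
  mass_kg <- voxel_mL * density_g_per_mL / 1000
  3600 * 1e6 * energy_MeV_per_decay * MeV_to_J / mass_kg * 1e6
}

#' Absorbed-dose map by local energy deposition
#'
#' Every decay deposits its charged-particle energy in the voxel where it
#' occurs — the appropriate default for a positron emitter whose betas
#' have millimetre range against multi-millimetre voxels, with the photon
#' component (annihilation quanta) left to kernel transport or neglected.
#'
#' @param tia A `tia_map` (MBq h/MBq per voxel).
#' @param nuclide A [nuclide_spec()]; its `mean_energy_per_decay_MeV`
#'   (yield folded in) drives the dose.
#' @param density_g_per_mL Tissue density (default 1).
#' @return A `dose_map`: 3-D `voxels` in uGy/MBq, `voxel_size_mm`,
#'   `mode = "local"`.
#' @export
dose_map_local <- function(tia, nuclide, density_g_per_mL = 1) {
  stopifnot(inherits(tia, "tia_map"), inherits(nuclide, "nuclide_spec"))
  if (density_g_per_mL <= 0) stop("density must be > 0", call. = FALSE)
  voxel_mL <- (tia$voxel_size_mm / 10)^3
  if (voxel_mL <= 0) stop("non-positive voxel volume", call. = FALSE)
  scale <- dose_scale_uGy(nuclide$mean_energy_per_decay_MeV, voxel_mL,
                          density_g_per_mL)
  structure(list(voxels = tia$voxels * scale,
                 voxel_size_mm = tia$voxel_size_mm, mode = "local"),
            class = "dose_map")
}

#' Absorbed-dose map by kernel convolution
#'
#' The energy released per voxel (decays times energy per decay) is
#' convolved with a dose-point kernel — a 3-D array, odd-sized on every
#' axis, whose entries are the fraction of released energy deposited at
#' each voxel offset — and divided by voxel mass. With a delta kernel
#' this reduces exactly to [dose_map_local()]. Only a programmatically
#' generated Gaussian toy kernel ships with the package
#' ([gaussian_kernel()]); validated transport kernels are user input.
#'
#' @param tia A `tia_map`.
#' @param kernel 3-D non-negative array, odd-sized per axis.
#' @param nuclide A [nuclide_spec()].
#' @param density_g_per_mL Tissue density.
#' @return A `dose_map` with `mode = "kernel"`.
#' @export
dose_map_kernel <- function(tia, kernel, nuclide, density_g_per_mL = 1) {
  stopifnot(inherits(tia, "tia_map"), inherits(nuclide, "nuclide_spec"))
  kd <- dim(kernel)
  if (length(kd) != 3L || any(kd %% 2 == 0)) {
    stop("kernel must be 3-D and odd-sized on every axis", call. = FALSE)
  }
  if (any(kernel < 0)) stop("kernel entries must be >= 0", call. = FALSE)
  voxel_mL <- (tia$voxel_size_mm / 10)^3
  scale <- dose_scale_uGy(nuclide$mean_energy_per_decay_MeV, voxel_mL,
                          density_g_per_mL)
  energy <- tia$voxels * scale  # uGy/MBq if all energy deposited locally
  dose <- fft_convolve3(energy, kernel)
  dose[dose < 0] <- 0  # FFT round-off can leave tiny negatives
  structure(list(voxels = dose, voxel_size_mm = tia$voxel_size_mm,
                 mode = "kernel"),
            class = "dose_map")
}

# zero-padded linear convolution via 3-D FFT, output cropped to dim(x)
fft_convolve3 <- function(x, k) {
  dx <- dim(x); dk <- dim(k)
  dp <- dx + dk - 1L
  xp <- array(0, dim = dp); xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, dim = dp); kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  conv <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    prod(dp)
  off <- (dk - 1L) / 2L
  conv[off[1] + seq_len(dx[1]), off[2] + seq_len(dx[2]), off[3] + seq_len(dx[3])]
}

#' Gaussian toy dose kernel
#'
#' Isotropic Gaussian sampled on an odd grid and normalized to sum to one
#' (all released energy deposited within the kernel support).
#'
#' @param sigma_vox Standard deviation in voxels.
#' @param half_width Kernel half-width in voxels (size `2*half_width+1`).
#' @return A 3-D array summing to 1.
#' @export
gaussian_kernel <- function(sigma_vox = 1, half_width = 3L) {
  g <- seq(-half_width, half_width)
  k <- outer(outer(exp(-g^2 / (2 * sigma_vox^2)),
                   exp(-g^2 / (2 * sigma_vox^2))),
             exp(-g^2 / (2 * sigma_vox^2)))
  dim(k) <- c(length(g), length(g), length(g))
  k / sum(k)
}

#' Delta kernel (all energy deposited in the source voxel)
#'
#' @return A 1x1x1 array containing 1.
#' @export
delta_kernel <- function() array(1, dim = c(1L, 1L, 1L))

#' Mean organ dose from a dose map
#'
#' Applies the organ segmentation to a dose map: the arithmetic mean dose
#' over each organ's voxels.
#'
#' @param dose A `dose_map`.
#' @param labels A [label_map()] on the same grid.
#' @return Named numeric vector, uGy/MBq per organ.
#' @export
organ_dose_from_map <- function(dose, labels) {
  stopifnot(inherits(dose, "dose_map"), inherits(labels, "label_map"))
  if (!identical(dim(dose$voxels), dim(labels$voxels))) {
    stop("dose map and label map grids differ", call. = FALSE)
  }
  flat <- as.vector(labels$voxels)
  out <- vapply(names(labels$legend), function(id_chr) {
    mean(dose$voxels[flat == as.integer(id_chr)])
  }, numeric(1))
  names(out) <- unname(labels$legend)
  out
}

#' Write a 3-D map (TIA or dose) as NIfTI
#'
#' @param map A `tia_map` or `dose_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$voxels,
                                     pixdim = rep(map$voxel_size_mm, 3)),
                     path)
  invisible(path)
}
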