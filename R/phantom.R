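#' Ground-truth organ kinetics
#'
#' Biological (decay-corrected) activity concentration of one organ,
#' modelled as a sum of two exponentials
#' `c(t) = a1 * exp(-mu1 * t) + a2 * exp(-mu2 * t)` (kBq/mL, t in s).
#' A negative `a2` with `mu2 >> mu1` encodes uptake-then-plateau: the
#' curve rises from `a1 + a2` at t = 0 and settles near `a1`.
#'
#' @param organ_id Positive integer label.
#' @param name Organ name.
#' @param a1,a2 Amplitudes (kBq/mL); `a2` may be negative.
#' @param mu1,mu2 Biological rates (s^-1, >= 0).
#' @param volume_mL Organ volume (mL, > 0); filled in by
#'   [generate_phantom()] from the voxel count.
#' @return An object of class `organ_kinetics`.
#' @export
organ_kinetics <- function(organ_id, name, a1, a2 = 0, mu1 = 0, mu2 = 0,
                           volume_mL = NA_real_) {
  stopifnot(organ_id >= 0, organ_id == round(organ_id))
  if (mu1 < 0 || mu2 < 0) stop("biological rates must be >= 0", call. = FALSE)
  kin <- structure(
    list(organ_id = as.integer(organ_id), name = name,
         a1 = a1, a2 = a2, mu1 = mu1, mu2 = mu2, volume_mL = volume_mL),
    class = "organ_kinetics"
  )
  tt <- seq(0, 420, by = 1)
  if (any(biological_curve(kin, tt) < -1e-9)) {
    stop("kinetics give a negative concentration on [0, 420] s", call. = FALSE)
  }
  kin
}

biological_curve <- function(kin, t) {
  kin$a1 * exp(-kin$mu1 * t) + kin$a2 * exp(-kin$mu2 * t)
}

#' Physical (decaying) activity concentration of an organ
#'
#' The biological biexponential multiplied by physical decay:
#' `(a1 exp(-mu1 t) + a2 exp(-mu2 t)) * exp(-lambda t)`.
#'
#' @param kin An [organ_kinetics()].
#' @param t Time(s) post injection (s, >= 0).
#' @param lambda Physical decay constant (s^-1).
#' @return Concentration (kBq/mL).
#' @export
true_activity <- function(kin, t, lambda) {
  stopifnot(all(t >= 0))
  biological_curve(kin, t) * exp(-lambda * t)
}

# Mean of exp(-r t) over [s, e); stable for r -> 0.
exp_frame_mean <- function(r, s, e) {
  dur <- e - s
  ifelse(abs(r) * dur < 1e-12, exp(-r * s),
         exp(-r * s) * (-expm1(-r * dur)) / (r * dur))
}

# Noiseless decay-corrected frame values of one organ: frame average of the
# physical curve, times the frame decay-correction factor.
frame_values_corrected <- function(kin, schedule, lambda) {
  f <- frame_decay_correction_factor(schedule$start_s, schedule$end_s, lambda,
                                     reference_time(schedule))
  phys <- kin$a1 * exp_frame_mean(kin$mu1 + lambda, schedule$start_s, schedule$end_s) +
          kin$a2 * exp_frame_mean(kin$mu2 + lambda, schedule$start_s, schedule$end_s)
  f * phys
}

#' Generate a digital phantom
#'
#' Lays out axis-aligned boxes and ellipsoids in an integer label volume.
#' Geometry is deliberately schematic: organ shape is irrelevant to the
#' dosimetry arithmetic, but adjacency (a heart wall shell wrapped around
#' the ventricular cavity) is supported so segmentation-boundary behaviour
#' is exercised. Voxels not claimed by any organ but inside the body box
#' get label 0 and, when the spec list carries a `body` entry, background
#' kinetics.
#'
#' @param organ_specs A list of per-organ specs as produced by
#'   [default_organ_specs()]: each a list with `organ_id`, `name`,
#'   `shape` ("box" or "ellipsoid"), `center` and `half_size` (voxel
#'   units), and kinetic parameters `a1`, `a2`, `mu1`, `mu2`.
#' @param grid_shape Integer triple, voxels per axis.
#' @param voxel_size_mm Isotropic voxel edge (mm).
#' @param jitter Lognormal coefficient of variation applied to each
#'   organ's amplitudes to create inter-replicate variability; 0 leaves
#'   the nominal kinetics untouched.
#' @param seed RNG seed for the jitter; the layout itself is
#'   deterministic.
#' @return A list with `labels` (a `label_map`) and `kinetics` (a list of
#'   [organ_kinetics()], volumes filled from voxel counts).
#' @export
generate_phantom <- function(organ_specs = default_organ_specs(),
                             grid_shape = c(40L, 40L, 60L),
                             voxel_size_mm = 4,
                             jitter = 0, seed = NULL) {
  stopifnot(length(grid_shape) == 3L)
  vox <- array(0L, dim = grid_shape)
  voxel_mL <- (voxel_size_mm / 10)^3  # mm^3 -> mL via cm^3
  idx <- arrayInd(seq_along(vox), dim(vox))

  legend <- character(0)
  body_spec <- NULL
  for (sp in organ_specs) {
    if (identical(sp$name, "body")) { body_spec <- sp; next }
    inside <- organ_mask(idx, sp)
    clash <- inside & vox[cbind(idx[, 1], idx[, 2], idx[, 3])] != 0L
    # a wall spec may carve out an interior hole instead of overlapping
    if (any(clash) && is.null(sp$carve_id)) {
      stop(sprintf("organ '%s' overlaps an already placed organ", sp$name),
           call. = FALSE)
    }
    if (!is.null(sp$carve_id)) {
      inside <- inside & vox[cbind(idx[, 1], idx[, 2], idx[, 3])] == 0L
    }
    vox[idx[inside, , drop = FALSE]] <- sp$organ_id
    legend[as.character(sp$organ_id)] <- sp$name
  }
  missing <- setdiff(names(legend),
                     as.character(unique(as.vector(vox))))
  if (length(missing) > 0) {
    stop("organ ids produced no voxels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(body_spec) && any(body_spec$half_size > 0)) {
    body_mask <- array(FALSE, dim = grid_shape)
    body_mask[idx[organ_mask(idx, body_spec), , drop = FALSE]] <- TRUE
    body_mask <- body_mask | vox != 0L
  } else {
    body_mask <- array(TRUE, dim = grid_shape)
  }
  labels <- label_map(vox, legend, voxel_size_mm = voxel_size_mm,
                      body_mask = body_mask)

  if (!is.null(seed)) set.seed(seed)
  kin <- lapply(organ_specs, function(sp) {
    scale <- if (jitter > 0) exp(stats::rnorm(1, -jitter^2 / 2, jitter)) else 1
    n_vox <- if (identical(sp$name, "body")) sum(body_mask & vox == 0L) else sum(vox == sp$organ_id)
    organ_kinetics(organ_id = if (identical(sp$name, "body")) 0L else sp$organ_id,
                   name = sp$name,
                   a1 = sp$a1 * scale, a2 = sp$a2 * scale,
                   mu1 = sp$mu1, mu2 = sp$mu2,
                   volume_mL = n_vox * voxel_mL)
  })
  names(kin) <- vapply(kin, function(k) k$name, character(1))
  list(labels = labels, kinetics = kin)
}

organ_mask <- function(idx, sp) {
  d <- sweep(idx, 2, sp$center)
  if (identical(sp$shape, "ellipsoid")) {
    rowSums(sweep(d, 2, sp$half_size, "/")^2) <= 1
  } else {
    abs(d[, 1]) <= sp$half_size[1] &
    abs(d[, 2]) <= sp$half_size[2] &
    abs(d[, 3]) <= sp$half_size[3]
  }
}

#' Integer organ label map
#'
#' @param voxels 3-D integer array; 0 marks unlabeled background body.
#' @param legend Named character vector mapping `organ_id` (as names) to
#'   organ names; ids must be unique and present in the array.
#' @param voxel_size_mm Isotropic voxel edge (mm).
#' @param body_mask Optional logical array marking body voxels (organs plus
#'   unlabeled body tissue); voxels outside are air. Default: whole grid.
#' @return An object of class `label_map`.
#' @export
label_map <- function(voxels, legend, voxel_size_mm = 4, body_mask = NULL) {
  stopifnot(length(dim(voxels)) == 3L)
  ids <- as.integer(names(legend))
  if (anyDuplicated(ids)) stop("duplicate organ ids in legend", call. = FALSE)
  if (is.null(body_mask)) body_mask <- array(TRUE, dim = dim(voxels))
  stopifnot(identical(dim(body_mask), dim(voxels)))
  structure(list(voxels = voxels, legend = legend,
                 voxel_size_mm = voxel_size_mm, body_mask = body_mask),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s voxels at %g mm, %d organs\n",
              paste(dim(x$voxels), collapse = "x"), x$voxel_size_mm,
              length(x$legend)))
  invisible(x)
}

#' Default whole-body organ layout and kinetics
#'
#' Twelve labelled structures covering the eleven segmented source organs
#' of a rubidium-chloride myocardial study (the heart is split into wall
#' and ventricular content), plus unlabeled background body tissue.
#' Plateau amplitudes are graded across organs; every curve rises rapidly
#' within the first minute and stabilises after about two minutes
#' (`a2 = -a1`, rise rates 0.02-0.08 s^-1, washout rates ~1e-4 s^-1).
#'
#' @return A list of organ spec lists consumed by [generate_phantom()].
#' @export
default_organ_specs <- function() {
  org <- function(id, name, shape, center, half, a1, mu2, mu1 = 1e-4,
                  carve_id = NULL) {
    list(organ_id = id, name = name, shape = shape, center = center,
         half_size = half, a1 = a1, a2 = -a1, mu1 = mu1, mu2 = mu2,
         carve_id = carve_id)
  }
  list(
    # heart content first, wall shell carved around it
    org(1L, "heart content", "ellipsoid", c(20, 20, 44), c(4, 4, 4), 300, 0.06),
    list(organ_id = 2L, name = "heart wall", shape = "ellipsoid",
         center = c(20, 20, 44), half_size = c(6, 6, 6),
         a1 = 90, a2 = -90, mu1 = 1e-4, mu2 = 0.04, carve_id = 1L),
    org(3L, "lungs", "box", c(8, 20, 44), c(4, 8, 8), 55, 0.05),
    org(4L, "liver", "ellipsoid", c(28, 20, 32), c(8, 8, 6), 65, 0.03),
    org(5L, "kidneys", "box", c(12, 20, 28), c(3, 4, 4), 110, 0.04),
    org(6L, "spleen", "ellipsoid", c(32, 30, 24), c(3, 3, 3), 75, 0.035),
    org(7L, "stomach", "box", c(18, 30, 32), c(3, 3, 3), 45, 0.03),
    org(8L, "adrenals", "box", c(12, 12, 33), c(2, 2, 1), 50, 0.04),
    org(9L, "gallbladder", "box", c(28, 10, 26), c(2, 2, 2), 35, 0.025),
    org(10L, "thyroid", "box", c(20, 20, 55), c(2, 2, 2), 60, 0.05),
    org(11L, "urinary bladder", "ellipsoid", c(20, 20, 10), c(3, 3, 3), 25, 0.02),
    org(12L, "uterus", "box", c(20, 28, 12), c(2, 2, 2), 30, 0.03),
    # body box leaves a 3-voxel air margin to every grid face
    list(organ_id = 0L, name = "body", shape = "box", center = c(20, 20, 30),
         half_size = c(16, 16, 26), a1 = 18, a2 = -18, mu1 = 1e-4, mu2 = 0.04,
         carve_id = NULL)
  )
}

#' Simulate dynamic PET frames over a phantom
#'
#' Every voxel of an organ receives the organ's noiseless decay-corrected
#' frame value: the frame average of the physically decaying curve, scaled
#' by [frame_decay_correction_factor()] — exactly what a scanner that
#' decay-corrects to scan start reports. With `noise_scale > 0`, each
#' voxel-frame value is replaced by a Poisson draw with expectation
#' `value * noise_scale * frame_duration`, rescaled back; this is a count
#' -statistics stand-in for tomographic noise, adequate for estimator
#' testing but without the spatial correlations of reconstructed images.
#'
#' @param labels A [label_map()].
#' @param kinetics List of [organ_kinetics()] (named by organ); an entry
#'   with `organ_id = 0` drives the unlabeled background body.
#' @param schedule A [frame_schedule()].
#' @param nuclide A [nuclide_spec()].
#' @param noise_scale Expected counts per (kBq/mL) per second of frame
#'   duration; 0 gives a noiseless image.
#' @param seed RNG seed for the noise; required for reproducibility when
#'   `noise_scale > 0`.
#' @return A `dynamic_image`: list with 4-D `voxels` (x, y, z, frame),
#'   `voxel_size_mm`, `schedule`, `decay_corrected = TRUE`.
#' @export
simulate_frames <- function(labels, kinetics, schedule, nuclide,
                            noise_scale = 0, seed = NULL) {
  stopifnot(inherits(labels, "label_map"), inherits(schedule, "frame_schedule"),
            inherits(nuclide, "nuclide_spec"))
  if (noise_scale < 0) stop("'noise_scale' must be >= 0", call. = FALSE)
  lambda <- decay_constant(nuclide)
  dims <- dim(labels$voxels)
  nf <- n_frames(schedule)
  img <- array(0, dim = c(dims, nf))
  flat <- as.vector(labels$voxels)
  nvox <- prod(dims)
  body_flat <- as.vector(labels$body_mask)
  for (kin in kinetics) {
    v <- frame_values_corrected(kin, schedule, lambda)
    sel <- if (kin$organ_id == 0L) which(flat == 0L & body_flat) else
      which(flat == kin$organ_id)
    if (length(sel) == 0 && kin$organ_id != 0L) {
      stop(sprintf("kinetics for organ id %d but no such voxels", kin$organ_id),
           call. = FALSE)
    }
    for (j in seq_len(nf)) img[sel + (j - 1) * nvox] <- v[j]
  }
  if (noise_scale > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (j in seq_len(nf)) {
      sl <- seq_len(nvox) + (j - 1) * nvox
      expect <- img[sl] * noise_scale * schedule$dur_s[j]
      img[sl] <- stats::rpois(nvox, expect) / (noise_scale * schedule$dur_s[j])
    }
  }
  img[img < 0] <- 0
  dynamic_image(img, voxel_size_mm = labels$voxel_size_mm,
                schedule = schedule, decay_corrected = TRUE)
}

#' Construct a dynamic image container
#'
#' @param voxels 4-D array (x, y, z, frame) of activity concentration
#'   (kBq/mL).
#' @param voxel_size_mm Isotropic voxel edge (mm).
#' @param schedule A [frame_schedule()]; its length must match the frame
#'   axis.
#' @param decay_corrected Logical: are values decay-corrected to the
#'   schedule's reference time?
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, voxel_size_mm, schedule,
                          decay_corrected = TRUE) {
  stopifnot(length(dim(voxels)) == 4L, inherits(schedule, "frame_schedule"))
  if (dim(voxels)[4] != n_frames(schedule)) {
    stop("frame axis length does not match the schedule", call. = FALSE)
  }
  structure(list(voxels = voxels, voxel_size_mm = voxel_size_mm,
                 schedule = schedule, decay_corrected = decay_corrected),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat(sprintf("<dynamic_image> %s voxels x %d frames at %g mm, %sdecay-corrected\n",
              paste(dim(x$voxels)[1:3], collapse = "x"), dim(x$voxels)[4],
              x$voxel_size_mm, if (x$decay_corrected) "" else "NOT "))
  invisible(x)
}

#' Simulate a single organ-level time-activity curve
#'
#' Organ-level shortcut past the voxel grid: the noiseless decay-corrected
#' frame values of one organ, optionally perturbed by the same
#' scaled-Poisson noise model as [simulate_frames()] applied to the organ
#' mean over `n_voxels` voxels. `frame_cv` parameterises the noise as the
#' approximate coefficient of variation of the organ-mean value in each
#' frame.
#'
#' @param kin An [organ_kinetics()].
#' @param schedule A [frame_schedule()].
#' @param nuclide A [nuclide_spec()].
#' @param frame_cv Target relative noise per frame value (0 = noiseless).
#' @param seed RNG seed.
#' @return Numeric vector of decay-corrected frame values (kBq/mL).
#' @export
simulate_tac <- function(kin, schedule, nuclide, frame_cv = 0, seed = NULL) {
  lambda <- decay_constant(nuclide)
  v <- frame_values_corrected(kin, schedule, lambda)
  if (frame_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    # Poisson with expectation 1/cv^2 has relative sd = cv
    n_counts <- pmax(v, 0) * 0 + 1 / frame_cv^2
    v <- v * stats::rpois(length(v), n_counts) / n_counts
  }
  pmax(v, 0)
}

#' Write a dynamic image and label map as NIfTI
#'
#' Frames go on the fourth axis; the ground truth (kinetics, schedule,
#' nuclide, seed) is written alongside as JSON so a simulated study is
#' self-describing.
#'
#' @param image A `dynamic_image`.
#' @param labels A [label_map()].
#' @param kinetics List of [organ_kinetics()] or NULL.
#' @param dir Output directory (created if absent).
#' @param extra Named list merged into the ground-truth JSON.
#' @return `dir`, invisibly.
#' @export
write_study <- function(image, labels, kinetics = NULL, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ps <- rep(image$voxel_size_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(image$voxels, pixdim = ps),
                     file.path(dir, "dynamic.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(labels$voxels, pixdim = ps),
                     file.path(dir, "labels.nii.gz"))
  truth <- c(list(
    schedule = lapply(seq_len(n_frames(image$schedule)), function(i)
      c(image$schedule$start_s[i], image$schedule$end_s[i])),
    decay_corrected = image$decay_corrected,
    legend = as.list(labels$legend),
    kinetics = lapply(kinetics, unclass)
  ), extra)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
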