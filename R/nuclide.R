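#' Nuclide physical constants
#'
#' Bundle the physical-decay and emission-energy constants of a positron
#' emitter. The decay constant is always derived from the half-life
#' (`lambda = ln 2 / T_half`), never stored, so the two cannot drift apart.
#'
#' @param name Nuclide name, e.g. `"Rb-82"`.
#' @param half_life_s Physical half-life in seconds (> 0). Rubidium-82
#'   has a 76 s half-life, which makes the decay bookkeeping in this
#'   package worth being careful about.
#' @param positron_yield Positrons emitted per decay, in `[0, 1]`.
#' @param mean_energy_per_decay_MeV Mean energy deposited locally per
#'   decay (MeV, >= 0): the charged-particle component, with the emission
#'   yield already folded in. Taken from nuclear-data compilations
#'   (ICRP 107 class); configuration, not a fitted quantity.
#' @param photon_fraction Fraction of the emitted energy carried by
#'   photons and therefore assigned to kernel transport rather than local
#'   deposition. 0 in local-deposition mode.
#'
#' @return An object of class `nuclide_spec`.
#' @seealso [decay_constant()], [read_nuclide()]
#' @export
#' @examples
#' rb82 <- nuclide_spec("Rb-82", half_life_s = 76,
#'                      positron_yield = 0.954,
#'                      mean_energy_per_decay_MeV = 1.41)
#' decay_constant(rb82)
nuclide_spec <- function(name, half_life_s, positron_yield = 1,
                         mean_energy_per_decay_MeV = 0,
                         photon_fraction = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_s) || length(half_life_s) != 1L ||
      !is.finite(half_life_s) || half_life_s <= 0) {
    stop("'half_life_s' must be a single positive number", call. = FALSE)
  }
  if (positron_yield < 0 || positron_yield > 1) {
    stop("'positron_yield' must lie in [0, 1]", call. = FALSE)
  }
  if (mean_energy_per_decay_MeV < 0) {
    stop("'mean_energy_per_decay_MeV' must be >= 0", call. = FALSE)
  }
  if (photon_fraction < 0 || photon_fraction > 1) {
    stop("'photon_fraction' must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name,
         half_life_s = half_life_s,
         positron_yield = positron_yield,
         mean_energy_per_decay_MeV = mean_energy_per_decay_MeV,
         photon_fraction = photon_fraction),
    class = "nuclide_spec"
  )
}

#' Physical decay constant
#'
#' @param spec A [nuclide_spec()].
#' @return The decay constant `ln 2 / half_life_s` in s^-1.
#' @export
decay_constant <- function(spec) {
  stopifnot(inherits(spec, "nuclide_spec"))
  log(2) / spec$half_life_s
}

#' @export
print.nuclide_spec <- function(x, ...) {
  cat(sprintf("<nuclide_spec> %s: T1/2 = %g s (lambda = %.6g s^-1), yield = %g, E_local = %g MeV/decay\n",
              x$name, x$half_life_s, decay_constant(x), x$positron_yield,
              x$mean_energy_per_decay_MeV))
  invisible(x)
}

#' Frame schedule of a dynamic acquisition
#'
#' The ordered, non-overlapping reconstruction frames of a dynamic PET
#' scan, each an accumulation interval `[start_s, end_s)`, plus the time
#' the scanner's decay correction refers to (default 0 = scan start,
#' which for a tracer infused at scan start is also injection start).
#'
#' @param start_s,end_s Numeric vectors of frame start/end times (s).
#' @param reference_time_s Decay-correction reference time (s).
#' @return An object of class `frame_schedule` (a data frame with columns
#'   `start_s`, `end_s`, `mid_s`, `dur_s` plus the reference time as an
#'   attribute).
#' @export
#' @examples
#' sched <- frame_schedule(c(0, 30, 60, 90, 120, 180, 270),
#'                         c(30, 60, 90, 120, 180, 270, 420))
#' sched$mid_s
frame_schedule <- function(start_s, end_s, reference_time_s = 0) {
  stopifnot(is.numeric(start_s), is.numeric(end_s),
            length(start_s) == length(end_s), length(start_s) >= 1L)
  if (any(end_s <= start_s)) {
    stop("every frame must satisfy start < end", call. = FALSE)
  }
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  if (any(start_s[-1] < end_s[-length(end_s)])) {
    stop("frames must be non-overlapping", call. = FALSE)
  }
  out <- data.frame(start_s = start_s, end_s = end_s,
                    mid_s = (start_s + end_s) / 2,
                    dur_s = end_s - start_s)
  attr(out, "reference_time_s") <- reference_time_s
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames over [%g, %g] s, decay reference t = %g s\n",
              nrow(x), min(x$start_s), max(x$end_s), attr(x, "reference_time_s")))
  print(as.data.frame(x), ...)
  invisible(x)
}

n_frames <- function(schedule) nrow(schedule)

reference_time <- function(schedule) attr(schedule, "reference_time_s")

#' Frame decay-correction factor
#'
#' Factor that converts the frame-averaged value of a physically decaying
#' signal into its value decay-corrected to the schedule's reference time:
#' for a frame `[s, e)` with duration `dt` and decay constant `lambda`,
#'
#'   `f = lambda * dt * exp(lambda * (s - ref)) / (1 - exp(-lambda * dt))`
#'
#' so that `f * mean(A0 * exp(-lambda * t), t in [s, e)) = A0` when the
#' reference time is 0. `f = exp(lambda * (s - ref))` in the limit
#' `lambda * dt -> 0` and exactly 1 when `lambda = 0`. Dividing by `f`
#' undoes the correction.
#'
#' @param start_s,end_s Frame boundaries (s), possibly vectors.
#' @param lambda Decay constant (s^-1, >= 0).
#' @param reference_time_s Decay-correction reference time (s).
#' @return Dimensionless correction factor(s).
#' @export
frame_decay_correction_factor <- function(start_s, end_s, lambda,
                                          reference_time_s = 0) {
  stopifnot(is.numeric(start_s), is.numeric(end_s), length(lambda) == 1L)
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  dur <- end_s - start_s
  if (any(dur <= 0)) stop("zero or negative frame duration", call. = FALSE)
  if (lambda == 0) return(rep(1, length(start_s)))
  x <- lambda * dur
  # expm1 keeps the factor accurate for lambda * dt << 1
  x / (-expm1(-x)) * exp(lambda * (start_s - reference_time_s))
}

#' Convert a duration in seconds to hours
#'
#' All internal times are seconds; time-integrated activity is reported in
#' hours. The conversion lives here and nowhere else.
#'
#' @param x Seconds.
#' @return Hours.
#' @export
seconds_to_hours <- function(x) x / 3600

#' Read a nuclide configuration from JSON
#'
#' The JSON carries the [nuclide_spec()] fields. A rubidium-82 file with
#' the 76 s half-life ships with the package:
#' `system.file("extdata", "rb82.json", package = "dynodose")`.
#'
#' @param path Path to a JSON file.
#' @return A [nuclide_spec()].
#' @export
read_nuclide <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  nuclide_spec(name = cfg$name,
               half_life_s = cfg$half_life_s,
               positron_yield = cfg$positron_yield %||% 1,
               mean_energy_per_decay_MeV = cfg$mean_energy_per_decay_MeV %||% 0,
               photon_fraction = cfg$photon_fraction %||% 0)
}

#' Read a frame schedule from JSON
#'
#' Expects a JSON array of `[start_s, end_s]` pairs, optionally wrapped in
#' an object with fields `frames` and `reference_time_s`. The bundled
#' `quadra_7frame.json` holds the seven-frame whole-body dynamic schedule
#' (0-30, 30-60, 60-90, 90-120, 120-180, 180-270, 270-420 s).
#'
#' @param path Path to a JSON file.
#' @return A [frame_schedule()].
#' @export
read_frame_schedule <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- 0
  if (is.list(cfg) && !is.null(cfg$frames)) {
    ref <- cfg$reference_time_s %||% 0
    cfg <- cfg$frames
  }
  m <- matrix(unlist(cfg), ncol = 2, byrow = !is.matrix(cfg))
  if (is.matrix(cfg)) m <- cfg
  frame_schedule(m[, 1], m[, 2], reference_time_s = ref)
}

#' The bundled seven-frame dynamic schedule
#'
#' @return A [frame_schedule()] with frames 0-30, 30-60, 60-90, 90-120,
#'   120-180, 180-270 and 270-420 s.
#' @export
default_schedule <- function() {
  read_frame_schedule(system.file("extdata", "quadra_7frame.json",
                                  package = "dynodose", mustWork = TRUE))
}

#' The bundled rubidium-82 nuclide configuration
#'
#' @return A [nuclide_spec()] for Rb-82 (half-life 76 s).
#' @export
default_nuclide <- function() {
  read_nuclide(system.file("extdata", "rb82.json",
                           package = "dynodose", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
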