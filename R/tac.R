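#' Per-organ time-activity curve table
#'
#' One row per organ per frame, holding the mean activity concentration
#' over the organ's voxels. The decay-correction state and the injected
#' activity travel with the table so downstream stages cannot misapply
#' either. Concentrations stay in kBq/mL throughout; organ activity in
#' MBq is derived on demand and normalization by the injected activity
#' happens only when time-integrated activity is computed.
#'
#' @param df Data frame with columns `organ_id`, `organ`, `frame`,
#'   `mean_kBq_per_mL`, `volume_mL`.
#' @param schedule A [frame_schedule()].
#' @param decay_corrected Logical.
#' @param injected_MBq Injected activity (MBq, > 0).
#' @return An object of class `tac_table` (a data frame with attributes).
#' @export
tac_table <- function(df, schedule, decay_corrected, injected_MBq) {
  need <- c("organ_id", "organ", "frame", "mean_kBq_per_mL", "volume_mL")
  stopifnot(all(need %in% names(df)), inherits(schedule, "frame_schedule"))
  if (!is.numeric(injected_MBq) || injected_MBq <= 0) {
    stop("'injected_MBq' must be > 0", call. = FALSE)
  }
  if (any(df$mean_kBq_per_mL < 0)) {
    stop("negative mean concentration in TAC table", call. = FALSE)
  }
  if (anyDuplicated(df[, c("organ_id", "frame")])) {
    stop("duplicate (organ, frame) rows", call. = FALSE)
  }
  per_organ <- table(df$organ_id)
  if (any(per_organ != n_frames(schedule))) {
    stop("every organ needs exactly one row per frame", call. = FALSE)
  }
  df$mid_s <- schedule$mid_s[df$frame]
  structure(df,
            schedule = schedule,
            decay_corrected = decay_corrected,
            injected_MBq = injected_MBq,
            class = c("tac_table", "data.frame"))
}

tac_schedule <- function(tacs) attr(tacs, "schedule")
is_decay_corrected <- function(tacs) attr(tacs, "decay_corrected")
injected_activity <- function(tacs) attr(tacs, "injected_MBq")

#' Extract per-organ time-activity curves from a dynamic image
#'
#' For each organ in the label-map legend, the arithmetic mean
#' concentration over its voxels in every frame; volumes come from voxel
#' counts. The decay-correction state is inherited from the image.
#'
#' @param image A `dynamic_image`.
#' @param labels A [label_map()] on the same voxel grid.
#' @param injected_MBq Injected activity (MBq, > 0).
#' @return A [tac_table()].
#' @export
extract_tacs <- function(image, labels, injected_MBq) {
  stopifnot(inherits(image, "dynamic_image"), inherits(labels, "label_map"))
  if (!identical(dim(image$voxels)[1:3], dim(labels$voxels))) {
    stop("image and label map grids differ", call. = FALSE)
  }
  voxel_mL <- (labels$voxel_size_mm / 10)^3
  nf <- n_frames(image$schedule)
  nvox <- prod(dim(labels$voxels))
  flat <- as.vector(labels$voxels)
  rows <- lapply(names(labels$legend), function(id_chr) {
    id <- as.integer(id_chr)
    sel <- which(flat == id)
    if (length(sel) == 0) {
      stop(sprintf("organ '%s' (id %d) has no voxels", labels$legend[[id_chr]], id),
           call. = FALSE)
    }
    means <- vapply(seq_len(nf), function(j)
      mean(image$voxels[sel + (j - 1) * nvox]), numeric(1))
    data.frame(organ_id = id, organ = labels$legend[[id_chr]],
               frame = seq_len(nf), mean_kBq_per_mL = means,
               volume_mL = length(sel) * voxel_mL)
  })
  tac_table(do.call(rbind, rows), image$schedule,
            decay_corrected = image$decay_corrected,
            injected_MBq = injected_MBq)
}

#' Organ activity in MBq per frame
#'
#' @param tacs A [tac_table()].
#' @return The table with an `activity_MBq` column
#'   (`mean_kBq_per_mL * volume_mL / 1000`).
#' @export
organ_activity <- function(tacs) {
  tacs$activity_MBq <- tacs$mean_kBq_per_mL * tacs$volume_mL / 1000
  tacs
}

#' Append the total-body remainder pseudo-organ
#'
#' The remainder row carries, per frame, the whole-body activity not
#' accounted for by any segmented organ: whole-body activity minus the
#' summed organ activities, floored at zero. The whole body defaults to
#' every voxel of the image (a synthetic phantom's body box); a logical
#' `body_mask` on the image grid restricts it, e.g. to a body contour.
#'
#' @param tacs A [tac_table()] extracted from `image`.
#' @param image The `dynamic_image` the TACs came from.
#' @param body_mask Optional logical 3-D array selecting body voxels.
#' @param organ_id Integer id for the remainder row (default 9999).
#' @return The [tac_table()] with a "total body (remainder)" organ whose
#'   `mean_kBq_per_mL` is the remainder activity divided by the remainder
#'   volume (body volume minus segmented organ volume).
#' @export
add_remainder <- function(tacs, image, body_mask = NULL, organ_id = 9999L) {
  stopifnot(inherits(tacs, "tac_table"), inherits(image, "dynamic_image"))
  dims <- dim(image$voxels)[1:3]
  if (is.null(body_mask)) body_mask <- array(TRUE, dim = dims)
  if (is.logical(body_mask)) body_mask <- array(body_mask, dim = dims)
  if (!identical(dim(body_mask), dims)) {
    stop("body mask grid differs from the image grid", call. = FALSE)
  }
  voxel_mL <- attr(tacs, "voxel_mL") %||% NULL
  # infer voxel volume from any organ row: volume / voxel count is unknown
  # here, so recompute from the image voxel size if stored, else 1 mL
  voxel_mL <- (image$voxel_size_mm / 10)^3
  nf <- n_frames(tac_schedule(tacs))
  sel <- which(as.vector(body_mask))
  nvox <- prod(dims)
  body_MBq <- vapply(seq_len(nf), function(j)
    sum(image$voxels[sel + (j - 1) * nvox]) * voxel_mL / 1000, numeric(1))
  act <- organ_activity(tacs)
  organ_MBq <- vapply(seq_len(nf), function(j)
    sum(act$activity_MBq[act$frame == j]), numeric(1))
  remainder <- body_MBq - organ_MBq
  low <- remainder < -1e-3 * body_MBq
  if (any(low)) {
    warning("remainder activity negative beyond tolerance in ",
            sum(low), " frame(s); clamped to 0", call. = FALSE)
  }
  remainder <- pmax(remainder, 0)
  rem_volume <- length(sel) * voxel_mL -
    sum(tacs$volume_mL[!duplicated(tacs$organ_id)])
  rem_volume <- max(rem_volume, voxel_mL)
  df <- rbind(
    as.data.frame(tacs)[, c("organ_id", "organ", "frame",
                            "mean_kBq_per_mL", "volume_mL")],
    data.frame(organ_id = organ_id, organ = "total body (remainder)",
               frame = seq_len(nf),
               mean_kBq_per_mL = remainder * 1000 / rem_volume,
               volume_mL = rem_volume)
  )
  tac_table(df, tac_schedule(tacs),
            decay_corrected = is_decay_corrected(tacs),
            injected_MBq = injected_activity(tacs))
}

#' Remove (or restore) the decay correction of a TAC table
#'
#' `uncorrect_decay()` divides each frame value by
#' `exp(lambda * (midpoint - reference))`, restoring the physically
#' decaying signal while keeping the within-frame correction — the state
#' the kinetic integration needs. `recorrect_decay()` is its exact
#' inverse. Both refuse to run twice.
#'
#' @param tacs A [tac_table()].
#' @param lambda Physical decay constant (s^-1).
#' @return A [tac_table()] with the flag flipped.
#' @export
uncorrect_decay <- function(tacs, lambda) {
  stopifnot(inherits(tacs, "tac_table"))
  if (!is_decay_corrected(tacs)) {
    stop("TAC table is already decay-uncorrected", call. = FALSE)
  }
  sched <- tac_schedule(tacs)
  fac <- exp(-lambda * (sched$mid_s[tacs$frame] - reference_time(sched)))
  out <- tacs
  out$mean_kBq_per_mL <- tacs$mean_kBq_per_mL * fac
  attr(out, "decay_corrected") <- FALSE
  out
}

#' @rdname uncorrect_decay
#' @export
recorrect_decay <- function(tacs, lambda) {
  stopifnot(inherits(tacs, "tac_table"))
  if (is_decay_corrected(tacs)) {
    stop("TAC table is already decay-corrected", call. = FALSE)
  }
  sched <- tac_schedule(tacs)
  fac <- exp(lambda * (sched$mid_s[tacs$frame] - reference_time(sched)))
  out <- tacs
  out$mean_kBq_per_mL <- tacs$mean_kBq_per_mL * fac
  attr(out, "decay_corrected") <- TRUE
  out
}

#' Write / read a TAC table as CSV
#'
#' Columns: `organ_id, organ, frame_start_s, frame_end_s, mean_kBq_per_mL,
#' volume_mL, decay_corrected`; the injected activity is carried in a
#' comment-style first column header line via an `injected_MBq` column
#' repeated per row (CSV has no metadata slot).
#'
#' @param tacs A [tac_table()].
#' @param path Output CSV path.
#' @return `path` invisibly; `read_tac_csv()` returns a [tac_table()].
#' @export
write_tac_csv <- function(tacs, path) {
  sched <- tac_schedule(tacs)
  out <- data.frame(
    organ_id = tacs$organ_id, organ = tacs$organ,
    frame_start_s = sched$start_s[tacs$frame],
    frame_end_s = sched$end_s[tacs$frame],
    mean_kBq_per_mL = tacs$mean_kBq_per_mL,
    volume_mL = tacs$volume_mL,
    decay_corrected = is_decay_corrected(tacs),
    injected_MBq = injected_activity(tacs)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  frames <- unique(df[, c("frame_start_s", "frame_end_s")])
  frames <- frames[order(frames$frame_start_s), ]
  sched <- frame_schedule(frames$frame_start_s, frames$frame_end_s)
  df$frame <- match(df$frame_start_s, sched$start_s)
  tac_table(df[, c("organ_id", "organ", "frame", "mean_kBq_per_mL", "volume_mL")],
            sched,
            decay_corrected = all(df$decay_corrected),
            injected_MBq = df$injected_MBq[1])
}
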