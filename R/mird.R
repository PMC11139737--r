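#' Canonical organ-name normalization and aliases
#'
#' Dose tables, TIA tables and tissue-weight lists name the same organ in
#' different dialects ("Heart content", "heart_contents", "total body").
#' All cross-table joins go through this single normalizer: lower-case,
#' underscores, plus an explicit alias map for content/wall vocabulary and
#' the remainder pseudo-organ.
#'
#' @param x Character vector of organ names.
#' @return Canonical names.
#' @export
normalize_organ <- function(x) {
  y <- tolower(trimws(x))
  y <- gsub("[ /-]+", "_", y)
  aliases <- c(
    heart_content = "heart_contents",
    heart_ventricular_cavities = "heart_contents",
    stomach_content = "stomach_contents",
    gallbladder_content = "gallbladder_contents",
    urinary_bladder_content = "urinary_bladder_contents",
    lung = "lungs",
    "total_body_(remainder)" = "remainder",
    total_body = "remainder",
    remainder_of_body = "remainder"
  )
  hit <- y %in% names(aliases)
  y[hit] <- aliases[y[hit]]
  y
}

#' Load an S-value table
#'
#' Reads a CSV with header `phantom,source,target,s_mGy_per_MBq_h` into an
#' `svalue_table`. S-values are mean absorbed dose to the target organ per
#' unit cumulated activity in the source organ, for one reference phantom.
#' Organ names are normalized via [normalize_organ()]. Validation: no
#' negative S, no duplicate (source, target) pair; a self-dose S(T<-T)
#' smaller than some cross-dose S(T<-S) is physically suspect and draws a
#' warning.
#'
#' @param path CSV path.
#' @param phantom_id Optional filter when the file carries several
#'   phantoms.
#' @return An `svalue_table`: list with `phantom_id` and a data frame
#'   `entries` (`source`, `target`, `S`).
#' @export
load_svalues <- function(path, phantom_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phantom", "source", "target", "s_mGy_per_MBq_h")
  if (!all(need %in% names(df))) {
    stop("S-value CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(phantom_id)) df <- df[df$phantom == phantom_id, ]
  if (nrow(df) == 0) stop("no S-value rows for the requested phantom",
                          call. = FALSE)
  svalue_table(phantom_id = df$phantom[1],
               source = df$source, target = df$target,
               S = df$s_mGy_per_MBq_h)
}

#' Construct an S-value table in code
#'
#' @param phantom_id Phantom label.
#' @param source,target Organ name vectors.
#' @param S S-values (mGy per MBq h), >= 0.
#' @return An `svalue_table`.
#' @export
svalue_table <- function(phantom_id, source, target, S) {
  stopifnot(length(source) == length(target), length(source) == length(S))
  if (any(S < 0)) stop("negative S-value", call. = FALSE)
  entries <- data.frame(source = normalize_organ(source),
                        target = normalize_organ(target), S = S)
  if (anyDuplicated(entries[, c("source", "target")])) {
    stop("duplicate (source, target) S-value pair", call. = FALSE)
  }
  self <- entries[entries$source == entries$target, ]
  for (i in seq_len(nrow(self))) {
    tgt <- self$target[i]
    cross <- entries$S[entries$target == tgt & entries$source != tgt]
    if (length(cross) > 0 && any(cross > self$S[i])) {
      warning(sprintf("self-dose S(%s<-%s) smaller than some cross-dose",
                      tgt, tgt), call. = FALSE)
    }
  }
  structure(list(phantom_id = phantom_id, entries = entries),
            class = "svalue_table")
}

#' Look up an S-value
#'
#' @param s An `svalue_table`.
#' @param target,source Organ names (normalized internally).
#' @return S in mGy per MBq h (0 for pairs not in the table).
#' @export
get_svalue <- function(s, target, source) {
  e <- s$entries
  hit <- e$target == normalize_organ(target) &
         e$source == normalize_organ(source)
  if (!any(hit)) return(0)
  e$S[hit]
}

#' MIRD organ absorbed doses from a TIA table
#'
#' The MIRD schema: dose to target T is the sum over source organs S of
#' cumulated activity times S-value, `D(T) = sum_S TIA(S) * S(T<-S)`.
#' Every source row of the TIA table — including the remainder — must
#' resolve to a source the S-table knows, otherwise the computation stops
#' naming the organ: silently dropping a source would silently drop dose.
#' Sources are accumulated in sorted name order so the floating-point
#' result does not depend on row order.
#'
#' @param tia A `tia_table` (normalized TIA, MBq h/MBq).
#' @param s An `svalue_table`.
#' @param subject,condition Metadata carried into the report.
#' @return A `dose_report`: data frame `target`, `dose_uGy_per_MBq`, with
#'   attributes `phantom_id`, `subject`, `condition`.
#' @export
organ_doses <- function(tia, s, subject = NA_character_,
                        condition = NA_character_) {
  stopifnot(inherits(s, "svalue_table"))
  src_names <- normalize_organ(tia$organ)
  known_sources <- unique(s$entries$source)
  unresolved <- setdiff(src_names, known_sources)
  if (length(unresolved) > 0) {
    if ("remainder" %in% unresolved) {
      stop("S-value table has no 'remainder' source row; the total-body ",
           "remainder cannot be dropped silently", call. = FALSE)
    }
    stop("TIA sources not in the S-value table: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  targets <- sort(unique(s$entries$target))
  tia_by_src <- stats::setNames(tia$tia_MBq_h_per_MBq, src_names)
  tia_by_src <- tia_by_src[order(names(tia_by_src))]
  dose <- vapply(targets, function(tg) {
    e <- s$entries[s$entries$target == tg, ]
    sv <- stats::setNames(e$S, e$source)[names(tia_by_src)]
    sv[is.na(sv)] <- 0
    # mGy/(MBq h) * MBq h/MBq * 1000 -> uGy/MBq
    sum(tia_by_src * sv) * 1000
  }, numeric(1))
  structure(data.frame(target = targets, dose_uGy_per_MBq = unname(dose)),
            phantom_id = s$phantom_id, subject = subject,
            condition = condition,
            class = c("dose_report", "data.frame"))
}

#' Load ICRP-103 tissue weighting factors
#'
#' CSV schema `organ,w_T`; one row may be named `remainder`, whose weight
#' is shared over the remainder organs actually present in a report (mean
#' of their equivalent doses, the ICRP 103 remainder rule). Weights must
#' sum to exactly 1.
#'
#' @param path CSV path; default: bundled ICRP-103 factors.
#' @param remainder_organs Organs covered by the remainder weight.
#' @return A `tissue_weights` object.
#' @export
load_tissue_weights <- function(path = system.file("extdata", "icrp103_weights.csv",
                                                   package = "dynodose",
                                                   mustWork = TRUE),
                                remainder_organs = icrp103_remainder_organs()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("organ", "w_T") %in% names(df)))
  tissue_weights(df$organ, df$w_T, remainder_organs)
}

#' @rdname load_tissue_weights
#' @param organ,w_T Vectors of organ names and weighting factors.
#' @export
tissue_weights <- function(organ, w_T, remainder_organs = icrp103_remainder_organs()) {
  if (abs(sum(w_T) - 1) > 1e-9) {
    stop(sprintf("tissue weighting factors must sum to 1 (got %.6f)",
                 sum(w_T)), call. = FALSE)
  }
  structure(list(weights = stats::setNames(w_T, normalize_organ(organ)),
                 remainder_organs = normalize_organ(remainder_organs)),
            class = "tissue_weights")
}

#' ICRP-103 remainder organ list
#'
#' @return Character vector of the organs sharing the remainder weight.
#' @export
icrp103_remainder_organs <- function() {
  c("adrenals", "extrathoracic_region", "gallbladder_wall", "heart_wall",
    "kidneys", "lymphatic_nodes", "muscle", "oral_mucosa", "pancreas",
    "prostate", "small_intestine_wall", "spleen", "thymus", "uterus")
}

#' Effective dose from an organ-dose report
#'
#' `E = sum_T w_T * H_T`, with equivalent dose `H_T` equal to absorbed
#' dose times the radiation weighting factor (1 for the photons and
#' electrons of a positron emitter). Named tissues absent from the report
#' (e.g. sex-specific organs of the other phantom) contribute zero with a
#' warning; the remainder weight is applied to the mean equivalent dose of
#' the remainder organs present.
#'
#' @param report A `dose_report` (or named numeric vector of uGy/MBq).
#' @param weights A `tissue_weights` object.
#' @param radiation_weighting Radiation weighting factor (default 1).
#' @return Effective dose in uSv/MBq.
#' @export
effective_dose <- function(report, weights, radiation_weighting = 1) {
  stopifnot(inherits(weights, "tissue_weights"))
  if (inherits(report, "dose_report")) {
    doses <- stats::setNames(report$dose_uGy_per_MBq,
                             normalize_organ(report$target))
  } else {
    doses <- stats::setNames(as.numeric(report), normalize_organ(names(report)))
  }
  H <- doses * radiation_weighting
  w <- weights$weights
  named <- setdiff(names(w), "remainder")
  missing <- setdiff(named, names(H))
  missing <- missing[w[missing] > 0]
  if (length(missing) > 0) {
    warning("tissues absent from the report contribute 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  E <- sum(w[named] * ifelse(named %in% names(H), H[named], 0), na.rm = TRUE)
  if ("remainder" %in% names(w)) {
    present <- intersect(weights$remainder_organs, names(H))
    if (length(present) > 0) {
      E <- E + w[["remainder"]] * mean(H[present])
    }
  }
  unname(E)  # uGy/MBq * dimensionless = uSv/MBq for w_R = 1
}

#' Rest-vs-stress relative difference
#'
#' `100 * (rest - stress) / stress`, the sign convention under which a
#' higher rest dose gives a positive difference.
#'
#' @param rest_value,stress_value Paired values; `stress_value > 0`.
#' @param digits Decimal places for reporting (NULL = unrounded).
#' @return Percent difference.
#' @export
rest_stress_relative_difference <- function(rest_value, stress_value,
                                            digits = 1) {
  if (any(stress_value <= 0)) {
    stop("'stress_value' must be > 0", call. = FALSE)
  }
  out <- 100 * (rest_value - stress_value) / stress_value
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Min-max dose range of one organ across reports
#'
#' @param doses A data frame with an `organ` (or `target`) column and one
#'   numeric column per subject/condition; NA cells (organ not applicable
#'   for a phantom) are ignored.
#' @param organ Organ name (normalized before matching).
#' @return Named vector `c(min = , max = )` in the units of the table.
#' @export
dose_range_summary <- function(doses, organ) {
  name_col <- intersect(c("organ", "target"), names(doses))[1]
  if (is.na(name_col)) stop("no organ/target column", call. = FALSE)
  hit <- normalize_organ(doses[[name_col]]) == normalize_organ(organ)
  if (!any(hit)) stop(sprintf("organ '%s' absent from the table", organ),
                      call. = FALSE)
  vals <- unlist(doses[hit, vapply(doses, is.numeric, logical(1)), drop = FALSE])
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("organ has no numeric dose values", call. = FALSE)
  c(min = min(vals), max = max(vals))
}
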