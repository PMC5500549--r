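# Gel lane traces: ladder calibration, length assignment, percentile
# processivity under single-hit trap conditions.

#' Construct a gel lane trace
#'
#' @param migration migration coordinate (pixels or mm), strictly increasing.
#' @param intensity non-negative intensities (a.u.).
#' @param label lane label.
#' @param role \code{"sample"} or \code{"ladder"}.
#' @return data frame of class \code{lane_trace}.
#' @export
lane_trace <- function(migration, intensity, label = "", role = "sample") {
  if (is.unsorted(migration, strictly = TRUE))
    stop("migration coordinates must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  out <- data.frame(migration = migration, intensity = intensity)
  attr(out, "label") <- label
  attr(out, "role") <- match.arg(role, c("sample", "ladder"))
  class(out) <- c("lane_trace", "data.frame")
  out
}

#' Read / write a lane trace CSV (migration, intensity)
#' @param path CSV path.
#' @param label,role passed to \code{\link{lane_trace}}.
#' @export
read_lane_trace <- function(path, label = basename(path), role = "sample") {
  x <- utils::read.csv(path)
  lane_trace(x[[1L]], x[[2L]], label = label, role = role)
}

#' @rdname read_lane_trace
#' @param lane a \code{lane_trace}.
#' @export
write_lane_trace <- function(lane, path) {
  utils::write.csv(as.data.frame(lane), path, row.names = FALSE)
  invisible(path)
}

#' Calibrate a marker ladder lane
#'
#' Detects ladder band peaks (local maxima above a noise floor), matches
#' them in migration order to the known fragment lengths (longest fragment
#' migrates least), and fits the log-linear denaturing-PAGE mobility model
#' \deqn{migration = a - b \log(length)}
#' by least squares.
#'
#' @param ladder a \code{\link{lane_trace}}.
#' @param known_lengths marker fragment lengths in nt.
#' @param noise_floor_frac peaks below this fraction of the lane maximum are
#'   ignored (default 0.1).
#' @return object of class \code{ladder_calibration} with the fitted
#'   \code{a}, \code{b}, anchor table and residuals.
#' @export
calibrate_ladder <- function(ladder, known_lengths, noise_floor_frac = 0.1) {
  known_lengths <- sort(as.numeric(known_lengths), decreasing = TRUE)
  if (length(known_lengths) < 2L) stop("need at least 2 ladder lengths")
  pk <- pracma::findpeaks(ladder$intensity,
                          minpeakheight = noise_floor_frac * max(ladder$intensity))
  if (is.null(pk)) stop("no ladder peaks detected above the noise floor")
  mig <- sort(ladder$migration[pk[, 2L]])
  if (length(mig) != length(known_lengths))
    stop("matching error: detected ", length(mig), " ladder peaks but ",
         length(known_lengths), " known lengths were given")
  anchors <- data.frame(migration = mig, length = known_lengths)
  fit <- lm(migration ~ log(length), data = anchors)
  b <- -unname(coef(fit)[2L])
  if (!(b > 0))
    stop("calibration error: mobility model is not monotone decreasing in length")
  structure(list(a = unname(coef(fit)[1L]), b = b, anchors = anchors,
                 residuals = unname(residuals(fit)), model = fit),
            class = "ladder_calibration")
}

#' @export
print.ladder_calibration <- function(x, ...) {
  cat(sprintf(
    "ladder_calibration: migration = %.3f - %.3f log(length); %d anchors, max |resid| %.3g\n",
    x$a, x$b, nrow(x$anchors), max(abs(x$residuals))))
  invisible(x)
}

#' Convert between migration and fragment length
#' @param cal a \code{ladder_calibration}.
#' @param migration,length values to convert.
#' @return lengths in nt / migration coordinates.
#' @export
migration_to_length <- function(cal, migration) exp((cal$a - migration) / cal$b)

#' @rdname migration_to_length
#' @export
length_to_migration <- function(cal, length) cal$a - cal$b * log(length)

#' Map a lane trace onto the length axis
#'
#' Each trace sample is mapped through the inverse mobility calibration to
#' an apparent length, shifted by \code{-offset} (the fluorophore mobility
#' offset, so the unextended labelled primer maps to its true length), and
#' re-binned to integer nt conserving total intensity.
#'
#' @param lane a \code{\link{lane_trace}}.
#' @param cal a \code{\link{calibrate_ladder}} result.
#' @param offset additive mobility offset in nt (default 44: a 36-nt
#'   fluorescein-labelled primer running at an apparent ~80 nt).
#' @return data frame of class \code{length_distribution} with columns
#'   \code{length_nt}, \code{intensity}; samples outside the calibrated
#'   migration range are flagged in \code{attr(, "extrapolated")}.
#' @export
assign_lengths <- function(lane, cal, offset = 44) {
  app <- migration_to_length(cal, lane$migration)
  true_len <- app - offset
  outside <- lane$migration < min(cal$anchors$migration) |
    lane$migration > max(cal$anchors$migration)
  bins <- round(true_len)
  agg <- tapply(lane$intensity, bins, sum)
  out <- data.frame(length_nt = as.integer(names(agg)),
                    intensity = as.numeric(agg))
  out <- out[order(out$length_nt), ]
  rownames(out) <- NULL
  attr(out, "offset") <- offset
  attr(out, "extrapolated") <- sum(outside & lane$intensity > 0)
  class(out) <- c("length_distribution", "data.frame")
  out
}

#' Percentile processivity estimate
#'
#' Restricts the length distribution to extended products (length strictly
#' greater than the primer), converts to extension length (product −
#' primer), and reports the intensity-weighted percentile: the smallest
#' extension whose cumulative normalized intensity reaches
#' \code{percentile}.
#'
#' @param distribution a \code{\link{assign_lengths}} result (or data frame
#'   with \code{length_nt}, \code{intensity}).
#' @param primer_length primer length in nt.
#' @param percentile distribution fraction reported as the processivity
#'   (default 0.85).
#' @return object of class \code{processivity_estimate}: \code{estimate}
#'   (nt of extension), \code{extended_fraction}, \code{percentile},
#'   \code{primer_length}, \code{note}. No intensity above the primer band
#'   gives a "no extension" result with estimate 0, not an error.
#' @export
processivity_estimate <- function(distribution, primer_length,
                                  percentile = 0.85) {
  if (nrow(distribution) == 0L) stop("empty length distribution")
  total <- sum(distribution$intensity)
  ext <- distribution[distribution$length_nt > primer_length, , drop = FALSE]
  ext_total <- sum(ext$intensity)
  mk <- function(est, note = NA_character_) {
    structure(list(percentile = percentile, estimate = est,
                   extended_fraction = if (total > 0) ext_total / total else 0,
                   primer_length = primer_length,
                   offset = attr(distribution, "offset") %||% NA_real_,
                   note = note),
              class = "processivity_estimate")
  }
  if (ext_total <= 0) return(mk(0, "no extension"))
  ext <- ext[order(ext$length_nt), ]
  cum <- cumsum(ext$intensity) / ext_total
  i <- which(cum >= percentile - 1e-12)[1L]
  mk(ext$length_nt[i] - primer_length)
}

#' @export
print.processivity_estimate <- function(x, ...) {
  cat(sprintf(
    "processivity_estimate: %g nt at the %.0f percentile (extended fraction %.2f)%s\n",
    x$estimate, 100 * x$percentile, x$extended_fraction,
    if (!is.na(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Single-hit (trap) condition check
#'
#' Flags the assay regime: "single-hit" when the enzyme is limiting
#' (below the primer-template concentration) and the unlabelled competitor
#' trap is in at least 400-fold excess; otherwise "multi-hit" with a note.
#'
#' @param enzyme_nM enzyme concentration (nM).
#' @param pt_nM primer-template concentration (nM).
#' @param trap_fold fold excess of the trap DNA.
#' @return list with \code{regime} and \code{note}.
#' @export
single_hit_check <- function(enzyme_nM, pt_nM, trap_fold) {
  if (enzyme_nM < pt_nM && trap_fold >= 400)
    list(regime = "single-hit",
         note = sprintf("limiting enzyme (%g nM < %g nM P-T), %g-fold trap",
                        enzyme_nM, pt_nM, trap_fold))
  else list(regime = "multi-hit",
            note = if (trap_fold < 400)
              sprintf("trap excess %g-fold < 400-fold: rebinding not suppressed",
                      trap_fold)
            else sprintf("enzyme (%g nM) not limiting vs %g nM P-T",
                         enzyme_nM, pt_nM))
}
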