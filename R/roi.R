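#' Mean signal over a rectangular ROI
#'
#' Arithmetic mean of the pixels inside a 0-based, half-open rectangle
#' `c(x0, y0, width, height)` (x = column, y = row): columns
#' `x0 .. x0+width-1` and rows `y0 .. y0+height-1` in 0-based terms.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param roi Integer vector `c(x0, y0, width, height)`, 0-based.
#' @return Mean pixel value.
#' @export
roi_mean <- function(image, roi) {
  stopifnot(is.matrix(image), length(roi) == 4)
  x0 <- roi[1]; y0 <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w < 1 || h < 1) stop("ROI is degenerate")
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(image) || y0 + h > nrow(image))
    stop("ROI extends outside the image")
  mean(image[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)])
}

#' Read rectangular ROIs from a JSON sidecar
#'
#' Expects a JSON array of objects with fields `name`, `x0`, `y0`, `width`,
#' `height` (0-based pixel coordinates).
#'
#' @param path Path to the JSON file.
#' @return Named list of `c(x0, y0, width, height)` vectors.
#' @export
read_roi_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  out <- lapply(seq_len(nrow(spec)), function(i)
    c(spec$x0[i], spec$y0[i], spec$width[i], spec$height[i]))
  names(out) <- spec$name
  out
}

#' Liver-to-muscle signal-intensity ratio
#'
#' The SIR statistic `SI_L / SI_M`. The muscle reference makes the ratio
#' invariant to the arbitrary overall scanner signal scale.
#'
#' @param si_liver Mean liver ROI signal.
#' @param si_muscle Mean muscle ROI signal; must be positive.
#' @return The dimensionless ratio; vectorized.
#' @export
compute_sir <- function(si_liver, si_muscle) {
  if (any(si_muscle <= 0))
    stop("muscle reference signal must be positive")
  si_liver / si_muscle
}

#' Censor examinations whose liver signal reaches background
#'
#' Splits records into those with liver signal above the floor and those at
#' or below it (where the SIR carries no iron information and the
#' calibration is not invertible). Order is preserved and the two parts
#' partition the input exactly.
#'
#' @param records Cohort or examination data frame (see [as_exams()]).
#' @param floor Signal floor; default 25 signal units. The alternative
#'   `floor = k * sigma * sqrt(pi/2)` ties the floor to k times the Rayleigh
#'   background mean (use [background_floor()]).
#' @return List with data frames `kept` and `censored`.
#' @export
censor_low_signal <- function(records, floor = 25) {
  stopifnot(floor >= 0)
  exams <- as_exams(records)
  low <- exams$si_liver <= floor
  list(kept = exams[!low, , drop = FALSE],
       censored = exams[low, , drop = FALSE])
}

#' Background-derived censoring floor
#'
#' `k` times the Rayleigh mean `sigma * sqrt(pi/2)` of the background noise.
#'
#' @param sigma Background noise level (signal units).
#' @param k Multiplier, default 2.
#' @return Signal floor.
#' @export
background_floor <- function(sigma, k = 2) {
  stopifnot(sigma >= 0, k >= 0)
  k * sigma * sqrt(pi / 2)
}
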