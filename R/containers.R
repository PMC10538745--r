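# Core data containers shared across the pipeline stages.

#' Marker trajectory container
#'
#' @param marker_names character vector.
#' @param times seconds, strictly increasing.
#' @param positions numeric array (frames x markers x 3), metres.
#' @param rate sampling rate in Hz (> 0).
#' @param missing_mask logical matrix (frames x markers); TRUE marks a gap.
#' @return object of class \code{marker_trajectories}.
#' @export
marker_trajectories <- function(marker_names, times, positions, rate,
                                missing_mask = NULL) {
  nt <- length(times); nm <- length(marker_names)
  stopifnot(rate > 0, dim(positions)[1L] == nt, dim(positions)[2L] == nm)
  if (nt > 1L && any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (is.null(missing_mask)) missing_mask <- matrix(FALSE, nt, nm)
  for (k in 1:3) {
    sl <- matrix(positions[, , k], nt, nm)
    if (any(!is.finite(sl[!missing_mask])))
      stopf("non-finite marker position outside the missing mask")
  }
  dimnames(positions) <- list(NULL, marker_names, c("x", "y", "z"))
  structure(list(marker_names = marker_names, times = times,
                 positions = positions, rate = rate,
                 missing_mask = missing_mask),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("<marker_trajectories: %d markers, %d frames @ %g Hz (%.2f s), %d gap cells>\n",
              length(x$marker_names), length(x$times), x$rate,
              diff(range(x$times)), sum(x$missing_mask)))
  invisible(x)
}

#' Force-plate series container
#'
#' One entry per foot/plate: 3-D force (N), centre of pressure (m) and free
#' vertical-axis torque (N.m) over time. Side labels are \code{"r"} (the
#' amputated side in right-side amputee trials) and \code{"l"}.
#'
#' @param times seconds.
#' @param plates named list (sides) of lists with \code{force} (n x 3),
#'   \code{cop} (n x 3), \code{torque} (length n).
#' @param rate sampling rate (Hz).
#' @param tol numerical tolerance on the non-negativity of vertical force.
#' @return object of class \code{forceplate_series}.
#' @export
forceplate_series <- function(times, plates, rate, tol = 1e-6) {
  for (s in names(plates)) {
    pl <- plates[[s]]
    stopifnot(nrow(pl$force) == length(times), nrow(pl$cop) == length(times),
              length(pl$torque) == length(times))
    if (any(pl$force[, 2L] < -tol * max(1, max(abs(pl$force[, 2L])))))
      stopf("vertical force on plate '%s' is negative beyond tolerance", s)
  }
  structure(list(times = times, plates = plates, rate = rate),
            class = "forceplate_series")
}

#' @export
print.forceplate_series <- function(x, ...) {
  cat(sprintf("<forceplate_series: plates [%s], %d frames @ %g Hz, peak Fy %.1f N>\n",
              paste(names(x$plates), collapse = ", "), length(x$times),
              x$rate, max(vapply(x$plates, function(p) max(p$force[, 2L]), 0))))
  invisible(x)
}

#' Reference trajectory container
#'
#' Generalized positions (and optionally velocities and accelerations) over
#' time for a set of model coordinates. Angles are radians, translations
#' metres.
#'
#' @param times seconds.
#' @param q matrix (frames x coords) with column names.
#' @param qd,qdd optional matching matrices.
#' @return object of class \code{reference_trajectory}.
#' @export
reference_trajectory <- function(times, q, qd = NULL, qdd = NULL) {
  stopifnot(nrow(q) == length(times), !is.null(colnames(q)))
  structure(list(times = times, q = q, qd = qd, qdd = qdd,
                 coords = colnames(q)),
            class = "reference_trajectory")
}

#' @export
print.reference_trajectory <- function(x, ...) {
  cat(sprintf("<reference_trajectory: %d coords x %d frames (%.2f s)%s>\n",
              ncol(x$q), length(x$times), diff(range(x$times)),
              if (is.null(x$qdd)) "" else ", analytic derivatives"))
  invisible(x)
}

# coerce/reorder a reference trajectory onto a coordinate set, deriving
# missing velocity/acceleration columns by filtered differentiation
as_reference_trajectory <- function(tr, coords, cutoff = 0) {
  stopifnot(inherits(tr, "reference_trajectory"))
  pick <- function(mat) {
    out <- matrix(0, length(tr$times), length(coords),
                  dimnames = list(NULL, coords))
    if (is.null(mat)) return(NULL)
    common <- intersect(coords, colnames(mat))
    out[, common] <- mat[, common, drop = FALSE]
    out
  }
  q <- pick(tr$q)
  qd <- pick(tr$qd); qdd <- pick(tr$qdd)
  if (is.null(qd) || is.null(qdd)) {
    rate <- 1 / mean(diff(tr$times))
    qf <- lowpass_cols(q, rate, cutoff)
    if (is.null(qd)) qd <- diff_central(qf, 1 / rate)
    if (is.null(qdd)) qdd <- diff_central(qd, 1 / rate)
    colnames(qd) <- colnames(qdd) <- coords
  }
  list(times = tr$times, q = q, qd = qd, qdd = qdd, coords = coords)
}

#' Gait trial container: synchronized markers + ground reactions
#'
#' @param markers a \code{marker_trajectories}.
#' @param grf a \code{forceplate_series}.
#' @param reference optional generating \code{reference_trajectory} (known
#'   for synthetic trials).
#' @param cycle optional cycle metadata (duration s, stance fraction,
#'   heel-strike times).
#' @return object of class \code{gait_trial}.
#' @export
gait_trial <- function(markers, grf, reference = NULL, cycle = NULL) {
  structure(list(markers = markers, grf = grf, reference = reference,
                 cycle = cycle), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial>\n  ")
  print(x$markers)
  cat("  ")
  print(x$grf)
  if (!is.null(x$cycle))
    cat(sprintf("  cycle: %.3f s, stance %.0f%%\n", x$cycle$duration,
                100 * x$cycle$stance_fraction))
  invisible(x)
}
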