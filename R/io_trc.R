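# TRC marker-file reader/writer. TRC is the tab-delimited motion-capture
# dialect: two metadata header rows, a marker-name row, an X/Y/Z component
# row, then Frame#/Time followed by one X/Y/Z triplet per marker. Positions
# are converted to metres on read according to the Units header field
# (Vicon exports default to mm) and written back in the requested units.

#' Read a TRC marker file
#'
#' @param path file path.
#' @return a \code{\link{marker_trajectories}} with positions in metres; gaps
#'   (blank or non-finite cells) are flagged in \code{missing_mask}, never
#'   silently zeroed.
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L || !grepl("^PathFileType", lines[1L]))
    stopf("malformed TRC header in '%s': line 1 must start with PathFileType", path)
  keys <- strsplit(lines[2L], "\t")[[1L]]
  vals <- strsplit(lines[3L], "\t")[[1L]]
  if (!"DataRate" %in% keys)
    stopf("malformed TRC header in '%s': line 2 lacks DataRate", path)
  meta <- setNames(as.list(vals[seq_along(keys)]), keys)
  rate <- as.numeric(meta$DataRate)
  units <- meta$Units %||% "mm"
  scale <- switch(units, mm = 1e-3, cm = 1e-2, m = 1,
                  stopf("unsupported Units '%s' in '%s'", units, path))
  name_row <- strsplit(lines[4L], "\t")[[1L]]
  markers <- name_row[-(1:2)]
  markers <- markers[markers != ""]
  nm <- length(markers)
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  nt <- length(data_lines)
  pos <- array(NA_real_, c(nt, nm, 3L))
  times <- numeric(nt)
  for (k in seq_len(nt)) {
    f <- strsplit(data_lines[k], "\t")[[1L]]
    times[k] <- as.numeric(f[2L])
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    length(v) <- 3L * nm
    pos[k, , ] <- matrix(v, nm, 3L, byrow = TRUE)
  }
  if (nt > 1L && any(diff(times) <= 0))
    stopf("non-monotonic time column in '%s'", path)
  miss <- apply(pos, c(1L, 2L), function(p) any(!is.finite(p)))
  pos <- pos * scale
  pos[is.na(pos)] <- 0  # masked cells carry a placeholder, mask is authoritative
  marker_trajectories(markers, times, pos, rate, missing_mask = miss)
}

#' Write a TRC marker file
#'
#' Inverse of \code{\link{read_trc}}: a round trip reproduces positions to
#' better than 1e-9 m. Masked cells are written as blanks.
#'
#' @param traj a \code{marker_trajectories}.
#' @param path output path.
#' @param units output units ("mm", "cm" or "m").
#' @return the path, invisibly.
#' @export
write_trc <- function(traj, path, units = "mm") {
  stopifnot(inherits(traj, "marker_trajectories"))
  if (length(traj$marker_names) == 0L) stopf("empty marker set")
  scale <- switch(units, mm = 1e3, cm = 1e2, m = 1,
                  stopf("unsupported Units '%s'", units))
  nm <- length(traj$marker_names); nt <- length(traj$times)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stopf("cannot open '%s' for writing", path)
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines("DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames", con)
  writeLines(sprintf("%.12g\t%.12g\t%d\t%d\t%s\t%.12g\t1\t%d",
                     traj$rate, traj$rate, nt, nm, units, traj$rate, nt), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(traj$marker_names, "", ""))),
                   collapse = "\t"), con)
  comp <- as.vector(vapply(seq_len(nm),
                           function(i) paste0(c("X", "Y", "Z"), i), character(3L)))
  writeLines(paste(c("", "", comp), collapse = "\t"), con)
  for (k in seq_len(nt)) {
    cells <- character(3L * nm)
    for (i in seq_len(nm)) {
      j <- 3L * (i - 1L)
      if (traj$missing_mask[k, i]) cells[j + 1:3] <- ""
      else cells[j + 1:3] <- sprintf("%.9f", traj$positions[k, i, ] * scale)
    }
    writeLines(paste(c(k, sprintf("%.9f", traj$times[k]), cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Fill short marker gaps by linear interpolation
#'
#' Gaps up to \code{max_gap} seconds are filled by per-component linear
#' interpolation and unmasked; frames with longer gaps keep their mask (the
#' inverse-kinematics stage excludes masked markers frame-wise).
#'
#' @param traj a \code{marker_trajectories}.
#' @param max_gap longest gap to fill, in seconds.
#' @return the repaired \code{marker_trajectories}.
#' @export
interpolate_marker_gaps <- function(traj, max_gap = 0.2) {
  dt <- 1 / traj$rate
  maxn <- floor(max_gap / dt)
  for (i in seq_along(traj$marker_names)) {
    m <- traj$missing_mask[, i]
    if (!any(m) || all(m)) next
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      if (r$lengths[g] > maxn) next
      a <- starts[g] - 1L; b <- ends[g] + 1L
      if (a < 1L || b > length(m)) next  # edge gaps are not extrapolated
      idx <- starts[g]:ends[g]
      for (k in 1:3) {
        traj$positions[idx, i, k] <- approx(
          traj$times[c(a, b)], traj$positions[c(a, b), i, k],
          xout = traj$times[idx])$y
      }
      traj$missing_mask[idx, i] <- FALSE
    }
  }
  traj
}
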