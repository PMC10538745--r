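# MOT/STO motion and force files: a small header (name, nRows, nColumns,
# inDegrees, endheader) followed by a tab-delimited table whose first column
# is time. Angle columns are converted to radians internally when the header
# declares degrees; the ground-reaction dialect uses per-foot columns
# ground_force_vx/vy/vz, ground_force_px/py/pz and ground_torque_x/y/z with
# a _1 suffix (or side tag) for the second plate.

#' Read a MOT/STO time-series table
#'
#' @param path file path.
#' @param angles_to_rad convert non-time columns to radians when the header
#'   declares \code{inDegrees=yes}. Force files ship with
#'   \code{inDegrees=no}, so conversion never touches them.
#' @return data.frame with a \code{time} column; attribute
#'   \code{"in_degrees"} records the header flag (values are always returned
#'   in internal units).
#' @export
read_mot <- function(path, angles_to_rad = TRUE) {
  lines <- readLines(path, warn = FALSE)
  eh <- grep("^endheader", lines)
  if (!length(eh)) stopf("malformed MOT header in '%s': no endheader", path)
  head <- lines[seq_len(eh[1L] - 1L)]
  getv <- function(key) {
    h <- grep(paste0("^", key, "\\s*="), head, value = TRUE)
    if (!length(h)) return(NULL)
    trimws(sub(".*=", "", h[1L]))
  }
  n_rows <- as.integer(getv("nRows") %||% NA)
  in_deg <- tolower(getv("inDegrees") %||% "no") == "yes"
  body <- lines[-(seq_len(eh[1L]))]
  body <- body[nzchar(trimws(body))]
  cols <- strsplit(body[1L], "\t")[[1L]]
  if (tolower(cols[1L]) != "time") stopf("first column of '%s' must be time", path)
  dat <- body[-1L]
  if (!is.na(n_rows) && length(dat) != n_rows)
    stopf("row-count mismatch in '%s': header says %d, found %d",
          path, n_rows, length(dat))
  mat <- do.call(rbind, lapply(dat, function(l) as.numeric(strsplit(l, "\t")[[1L]])))
  df <- as.data.frame(mat)
  names(df) <- cols
  if (in_deg && angles_to_rad) {
    ang <- setdiff(names(df), "time")
    df[ang] <- df[ang] * pi / 180
  }
  attr(df, "in_degrees") <- in_deg
  df
}

#' Write a MOT/STO time-series table
#'
#' @param table data.frame whose first column is \code{time} (internal
#'   units: radians, m, N, N.m).
#' @param path output path.
#' @param in_degrees write angle columns in degrees (converts all non-time
#'   columns; use FALSE for force tables).
#' @param name header name field.
#' @return the path, invisibly.
#' @export
write_mot <- function(table, path, in_degrees = FALSE, name = basename(path)) {
  stopifnot(tolower(names(table)[1L]) == "time")
  out <- table
  if (in_degrees) {
    ang <- setdiff(names(out), "time")
    out[ang] <- out[ang] * 180 / pi
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", nrow(out)),
               sprintf("nColumns=%d", ncol(out)),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(out), collapse = "\t")), con)
  apply(out, 1L, function(r) writeLines(paste(sprintf("%.12g", r), collapse = "\t"), con))
  invisible(path)
}

# default GRF column mapping; `suffix` distinguishes the two plates
grf_column_map <- function(side, suffix = "") {
  list(side = side,
       force = paste0("ground_force_v", c("x", "y", "z"), suffix),
       cop = paste0("ground_force_p", c("x", "y", "z"), suffix),
       torque = paste0("ground_torque_", c("x", "y", "z"), suffix))
}

#' Extract a force-plate series from a GRF table
#'
#' @param table data.frame from \code{\link{read_mot}}.
#' @param mapping list of per-plate column maps, as produced by the internal
#'   default (plate 1 unsuffixed = right/amputated side, plate 2 suffixed
#'   \code{_1} = left). Override to handle other dialects.
#' @param rate sampling rate; inferred from the time column when NULL.
#' @return a \code{\link{forceplate_series}}.
#' @export
as_forceplate_series <- function(table, mapping = NULL, rate = NULL) {
  if (is.null(mapping))
    mapping <- list(grf_column_map("r", ""), grf_column_map("l", "_1"))
  times <- table$time
  if (is.null(rate)) rate <- 1 / mean(diff(times))
  plates <- list()
  for (mp in mapping) {
    if (!all(c(mp$force, mp$cop) %in% names(table)))
      stopf("GRF table lacks columns for side '%s'", mp$side)
    tq <- if (all(mp$torque %in% names(table))) table[[mp$torque[3L]]] else numeric(length(times))
    plates[[mp$side]] <- list(
      force = as.matrix(table[mp$force]),
      cop = as.matrix(table[mp$cop]),
      torque = tq)
  }
  forceplate_series(times, plates, rate)
}

#' Write a force-plate series as a GRF MOT table
#'
#' @param grf a \code{\link{forceplate_series}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_grf_mot <- function(grf, path) {
  df <- data.frame(time = grf$times)
  sfx <- ""
  for (s in names(grf$plates)) {
    pl <- grf$plates[[s]]
    for (k in 1:3) df[[paste0("ground_force_v", c("x", "y", "z")[k], sfx)]] <- pl$force[, k]
    for (k in 1:3) df[[paste0("ground_force_p", c("x", "y", "z")[k], sfx)]] <- pl$cop[, k]
    df[[paste0("ground_torque_x", sfx)]] <- 0
    df[[paste0("ground_torque_y", sfx)]] <- 0
    df[[paste0("ground_torque_z", sfx)]] <- pl$torque
    sfx <- "_1"
  }
  write_mot(df, path, in_degrees = FALSE, name = "ground reaction forces")
  invisible(path)
}
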