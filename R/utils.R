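# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 2-D cross products in the sagittal plane (x forward, y up, z out of plane)
perp2 <- function(r) c(-r[2L], r[1L])        # z-hat x r
cross2z <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

rot2 <- function(phi) {
  c <- cos(phi); s <- sin(phi)
  matrix(c(c, s, -s, c), 2L, 2L)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

GRAVITY <- 9.80665  # m/s^2

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# trapezoidal integral of y(t)
trapz_int <- function(t, y) sum(diff(t) * (head(y, -1L) + tail(y, -1L)) / 2)

# linear interpolation of each column of a matrix onto new times
interp_cols <- function(times, mat, new_times) {
  out <- matrix(NA_real_, length(new_times), ncol(mat))
  for (j in seq_len(ncol(mat)))
    out[, j] <- approx(times, mat[, j], xout = new_times, rule = 2)$y
  colnames(out) <- colnames(mat)
  out
}
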