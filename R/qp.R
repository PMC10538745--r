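#' Solve a strictly convex quadratic program with box and equality constraints
#'
#' Minimizes \code{0.5 * t(x) %*% H %*% x + c %*% x} subject to
#' \code{Aeq %*% x == beq} and \code{lb <= x <= ub}. This is the work-horse
#' behind the per-frame muscle-redundancy problems: the static-optimization
#' stage poses torque-balance equalities over muscle activations and
#' prosthesis-actuator controls, and the computed-muscle-control allocation
#' poses a (soft or hard) acceleration-matching problem over all effectors.
#'
#' Box constraints are handled by a primal active-set method on the bounds
#' (variables pinned at a bound are eliminated; violated bounds are pinned in
#' blocks, wrongly pinned variables are released one at a time). Equality
#' constraints are enforced by an augmented-Lagrangian outer loop on the
#' row-normalized constraints, which keeps every inner solve strictly
#' positive definite and free of singular KKT systems. \code{H} must be
#' symmetric positive definite, so the minimizer is unique.
#'
#' @param H symmetric positive-definite matrix (n x n).
#' @param c linear term, length n.
#' @param lb,ub bounds, length n (may be -Inf/Inf).
#' @param Aeq,beq optional equality constraints (m x n, length m).
#' @param tol numerical tolerance on bounds and multiplier signs.
#' @param tol_eq relative tolerance on the equality residual.
#' @param max_outer augmented-Lagrangian iteration cap.
#' @return list with \code{x}, \code{lambda} (equality multipliers),
#'   \code{status} ("optimal", "infeasible" or "maxiter"), \code{eq_residual}
#'   (max abs equality violation) and \code{iterations} (inner iterations).
#' @export
solve_boxqp <- function(H, c, lb, ub, Aeq = NULL, beq = NULL,
                        tol = 1e-10, tol_eq = 1e-9, max_outer = 40L) {
  n <- length(c)
  stopifnot(nrow(H) == n, ncol(H) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stopf("solve_boxqp: lb > ub")

  if (is.null(Aeq) || nrow(Aeq) == 0L) {
    ans <- boxqp_active_set(H, c, lb, ub, tol = tol)
    return(list(x = ans$x, lambda = numeric(0), status = ans$status,
                eq_residual = 0, iterations = ans$iterations))
  }

  m <- nrow(Aeq)
  stopifnot(ncol(Aeq) == n, length(beq) == m)
  # row-normalize so the penalty scale is dimensionless
  rn <- sqrt(rowSums(Aeq^2))
  rn[rn < 1e-14] <- 1
  A <- Aeq / rn
  b <- beq / rn
  bscale <- max(1, max(abs(b)))

  mu <- 1e6
  lam <- numeric(m)
  pin <- NULL
  x <- clamp(numeric(n), lb, ub)
  iters <- 0L
  res_prev <- Inf
  AtA <- crossprod(A)
  for (outer in seq_len(max_outer)) {
    Hm <- H + mu * AtA
    cm <- c + as.numeric(crossprod(A, lam - mu * b))
    inner <- boxqp_active_set(Hm, cm, lb, ub, tol = tol, pin = pin)
    x <- inner$x; pin <- inner$pin
    iters <- iters + inner$iterations
    r <- as.numeric(A %*% x - b)
    res <- max(abs(r))
    if (res < tol_eq * bscale) {
      return(list(x = x, lambda = -(lam + mu * r) / rn, status = "optimal",
                  eq_residual = max(abs(Aeq %*% x - beq)),
                  iterations = iters))
    }
    lam <- lam + mu * r
    if (res > 0.25 * res_prev) {
      if (mu >= 1e12) {
        # constraints unattainable within the bounds
        return(list(x = x, lambda = -lam / rn, status = "infeasible",
                    eq_residual = max(abs(Aeq %*% x - beq)),
                    iterations = iters))
      }
      mu <- mu * 100
    }
    res_prev <- res
  }
  list(x = x, lambda = -lam / rn, status = "maxiter",
       eq_residual = max(abs(Aeq %*% x - beq)), iterations = iters)
}

# box-constrained strictly convex QP by primal active set on the bounds;
# `pin` (-1 lower / 0 free / +1 upper) may carry a warm start
boxqp_active_set <- function(H, c, lb, ub, tol = 1e-10, pin = NULL,
                             max_iter = NULL) {
  n <- length(c)
  # Jacobi equilibration: effector capacities span many orders of magnitude
  # (1 N.m reserves vs 1 MN.m prosthesis actuators)
  s <- sqrt(pmax(diag(H), 1e-30))
  H <- H / tcrossprod(s)
  c <- c / s
  lb <- lb * s
  ub <- ub * s
  if (is.null(max_iter)) max_iter <- 3L * n + 30L
  if (is.null(pin)) pin <- integer(n)
  pin[lb == ub] <- -1L
  x <- clamp(numeric(n), lb, ub)
  last_release <- -1L
  for (it in seq_len(max_iter)) {
    free <- which(pin == 0L)
    xc <- ifelse(pin == -1L, lb, ifelse(pin == 1L, ub, 0))
    nf <- length(free)
    if (nf > 0L) {
      rhs <- -c[free] - if (nf < n) H[free, -free, drop = FALSE] %*% xc[-free] else 0
      xf <- tryCatch(
        as.numeric(solve(H[free, free, drop = FALSE], rhs)),
        error = function(e) as.numeric(qr.solve(H[free, free, drop = FALSE],
                                                rhs, tol = 1e-16)))
    } else xf <- numeric(0)
    xtrial <- xc
    xtrial[free] <- xf
    vlo <- lb - xtrial
    vhi <- xtrial - ub
    vlo[pin != 0L] <- -Inf
    vhi[pin != 0L] <- -Inf
    if (max(vlo, vhi, -Inf) > tol) {
      pin[vlo > tol] <- -1L
      pin[vhi > tol] <- 1L
      next
    }
    x <- clamp(xtrial, lb, ub)
    grad <- as.numeric(H %*% x + c)
    rel_lo <- which(pin == -1L & lb < ub & grad < -tol)
    rel_hi <- which(pin == 1L & grad > tol)
    if (length(rel_lo) || length(rel_hi)) {
      cand <- c(rel_lo, rel_hi)
      i <- cand[which.max(abs(grad[cand]))]
      if (i == last_release && length(cand) > 1L)
        i <- cand[order(-abs(grad[cand]))][2L]  # simple anti-cycling
      pin[i] <- 0L
      last_release <- i
      next
    }
    return(list(x = x / s, pin = pin, status = "optimal", iterations = it))
  }
  list(x = x / s, pin = pin, status = "maxiter", iterations = max_iter)
}
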