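# Planar kinematic tree: the sagittal-plane engine behind forward
# kinematics, inverse kinematics, and the recursive Newton-Euler dynamics.
# Welded chains are collapsed into composite rigid bodies; revolute joints
# whose coordinate is locked or out of the sagittal set are frozen at
# neutral and absorbed into their parent.

# Build the dynamic tree from a model. Returns:
#   coords  - ordered sagittal unlocked coordinate names (the q vector)
#   bodies  - list(name, parent (index into bodies, 0 = ground), jtype
#             ("float"|"rev"), axis, loc (2), mass, com (2), izz, qidx)
#   seg2body - map from segment name to list(body, off) for markers
build_dynamic_tree <- function(model) {
  segs <- model$segments
  co <- model$coordinates
  # order segments topologically
  ord <- character(0)
  remaining <- segs$name
  while (length(remaining)) {
    ready <- remaining[segs$parent[match(remaining, segs$name)] %in% c("ground", ord)]
    if (!length(ready)) stopf("segment tree has a cycle")
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  segs <- segs[match(ord, segs$name), ]

  coord_of_joint <- function(j, kind) {
    rows <- co[co$joint == j & co$sagittal & !co$locked & co$kind == kind, ]
    rows$name
  }

  bodies <- list()
  coords <- character(0)
  body_of_seg <- list()   # segment name -> list(body = index, off = c(x, y))

  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    jt <- s$jtype
    if (jt == "rev") {
      cn <- coord_of_joint(s$joint, "rot")
      if (length(cn) == 0L) jt <- "weld"  # frozen joint
    }
    if (jt == "weld") {
      # collapse into the parent body at the (fixed) joint location
      p <- body_of_seg[[s$parent]]
      if (is.null(p)) stopf("weld joint to ground is not supported")
      off <- p$off + c(s$loc_x, s$loc_y)  # parent frame == body frame (no rotation)
      b <- bodies[[p$body]]
      comp <- composite_welded_body(data.frame(
        mass = c(b$mass, s$mass),
        com_x = c(b$com[1L], off[1L] + s$com_x),
        com_y = c(b$com[2L], off[2L] + s$com_y),
        izz = c(b$izz, s$izz)))
      b$mass <- comp$mass; b$com <- comp$com; b$izz <- comp$izz
      bodies[[p$body]] <- b
      body_of_seg[[s$name]] <- list(body = p$body, off = off)
      next
    }

    parent_idx <- if (s$parent == "ground") 0L else body_of_seg[[s$parent]]$body
    parent_off <- if (s$parent == "ground") c(0, 0) else body_of_seg[[s$parent]]$off
    if (jt == "float") {
      cn <- c(coord_of_joint(s$joint, "trans"), coord_of_joint(s$joint, "rot"))
      if (length(cn) != 3L)
        stopf("floating joint '%s' needs tx, ty and one rotation", s$joint)
      qidx <- length(coords) + 1:3
    } else {
      qidx <- length(coords) + 1L
    }
    coords <- c(coords, cn)
    bodies[[length(bodies) + 1L]] <- list(
      name = s$name, parent = parent_idx, jtype = jt, axis = s$axis,
      loc = parent_off + c(s$loc_x, s$loc_y),
      mass = s$mass, com = c(s$com_x, s$com_y), izz = s$izz, qidx = qidx)
    body_of_seg[[s$name]] <- list(body = length(bodies), off = c(0, 0))
  }

  list(coords = coords, n = length(coords), bodies = bodies,
       seg2body = body_of_seg)
}

# forward pass: poses (and optionally spatial velocities/accelerations)
# given q, qd, qdd over dyn$coords
tree_kinematics <- function(dyn, q, qd = NULL, qdd = NULL) {
  nb <- length(dyn$bodies)
  phi <- numeric(nb); om <- numeric(nb); al <- numeric(nb)
  x <- matrix(0, nb, 2L); v <- matrix(0, nb, 2L); a <- matrix(0, nb, 2L)
  need_v <- !is.null(qd); need_a <- !is.null(qdd)
  for (i in seq_len(nb)) {
    b <- dyn$bodies[[i]]
    if (b$jtype == "float") {
      it <- b$qidx[1:2]; ir <- b$qidx[3L]
      phi[i] <- b$axis * q[ir]
      x[i, ] <- q[it]
      if (need_v) { om[i] <- b$axis * qd[ir]; v[i, ] <- qd[it] }
      if (need_a) { al[i] <- b$axis * qdd[ir]; a[i, ] <- qdd[it] }
    } else {
      p <- b$parent
      pphi <- if (p > 0L) phi[p] else 0
      rl <- rot2(pphi) %*% b$loc
      x[i, ] <- (if (p > 0L) x[p, ] else c(0, 0)) + rl
      phi[i] <- pphi + b$axis * q[b$qidx]
      if (need_v) {
        pom <- if (p > 0L) om[p] else 0
        v[i, ] <- (if (p > 0L) v[p, ] else c(0, 0)) + pom * perp2(rl)
        om[i] <- pom + b$axis * qd[b$qidx]
      }
      if (need_a) {
        pom <- if (p > 0L) om[p] else 0
        pal <- if (p > 0L) al[p] else 0
        a[i, ] <- (if (p > 0L) a[p, ] else c(0, 0)) +
          pal * perp2(rl) - pom^2 * rl
        al[i] <- pal + b$axis * qdd[b$qidx]
      }
    }
  }
  list(phi = phi, x = x, om = om, v = v, al = al, a = a)
}

#' Forward kinematics: segment poses and virtual marker positions
#'
#' Composes the planar poses of all segments down the tree for a given
#' sagittal coordinate vector and places the model's virtual markers. Marker
#' lateral (z) offsets are carried through unchanged: the engine is
#' sagittal-plane, so out-of-plane coordinates do not move.
#'
#' @param model an \code{msk_model} with markers.
#' @param q named or ordered numeric vector over \code{dynamic_coords(model)}.
#' @param dyn optional pre-built dynamic tree (performance).
#' @return list with \code{poses} (data.frame: segment origin x, y and angle
#'   phi) and \code{markers} (matrix n x 3, rownames = marker names).
#' @export
forward_kinematics <- function(model, q, dyn = NULL) {
  if (is.null(dyn)) dyn <- build_dynamic_tree(model)
  q <- order_q(dyn, q)
  kin <- tree_kinematics(dyn, q)
  nb <- length(dyn$bodies)
  poses <- data.frame(segment = vapply(dyn$bodies, `[[`, "", "name"),
                      x = kin$x[, 1L], y = kin$x[, 2L], phi = kin$phi)
  mk <- model$markers
  out <- NULL
  if (!is.null(mk)) {
    out <- matrix(NA_real_, nrow(mk), 3L,
                  dimnames = list(mk$name, c("x", "y", "z")))
    for (i in seq_len(nrow(mk))) {
      sb <- dyn$seg2body[[mk$segment[i]]]
      if (is.null(sb)) stopf("marker '%s' on unknown segment '%s'",
                             mk$name[i], mk$segment[i])
      loc <- sb$off + c(mk$x[i], mk$y[i])
      w <- kin$x[sb$body, ] + rot2(kin$phi[sb$body]) %*% loc
      out[i, ] <- c(w, mk$z[i])
    }
  }
  list(poses = poses, markers = out, kin = kin, dyn = dyn)
}

# accept named q in any order, or unnamed in dyn order
order_q <- function(dyn, q) {
  if (!is.null(names(q))) {
    miss <- setdiff(dyn$coords, names(q))
    if (length(miss)) stopf("q missing coordinate(s): %s", paste(miss, collapse = ", "))
    q <- q[dyn$coords]
  } else if (length(q) != dyn$n) stopf("q has length %d, expected %d", length(q), dyn$n)
  as.numeric(q)
}

# 2 x n jacobian of a world point attached to body `bi` (world coords pt)
point_jacobian <- function(dyn, kin, bi, pt) {
  J <- matrix(0, 2L, dyn$n)
  i <- bi
  while (i > 0L) {
    b <- dyn$bodies[[i]]
    if (b$jtype == "float") {
      J[1L, b$qidx[1L]] <- 1
      J[2L, b$qidx[2L]] <- 1
      J[, b$qidx[3L]] <- J[, b$qidx[3L]] + b$axis * perp2(pt - kin$x[i, ])
    } else {
      J[, b$qidx] <- J[, b$qidx] + b$axis * perp2(pt - kin$x[i, ])
    }
    i <- b$parent
  }
  J
}

# 1 x n rotational jacobian of body bi
rot_jacobian <- function(dyn, bi) {
  J <- numeric(dyn$n)
  i <- bi
  while (i > 0L) {
    b <- dyn$bodies[[i]]
    J[b$qidx[length(b$qidx)]] <- J[b$qidx[length(b$qidx)]] + b$axis
    i <- b$parent
  }
  J
}

# generalized force of an external wrench (force F at world point pt plus
# free torque Tz) applied to body bi
generalized_external_force <- function(dyn, kin, bi, pt, F, Tz = 0) {
  as.numeric(crossprod(point_jacobian(dyn, kin, bi, pt), F)) +
    rot_jacobian(dyn, bi) * Tz
}
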