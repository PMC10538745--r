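#' Construct a musculoskeletal model object
#'
#' Low-level constructor assembling an \code{msk_model} from its component
#' tables. Most users call \code{\link{build_healthy_model}} or
#' \code{\link{apply_amputation}} instead; the constructor is exported so that
#' reduced models (single links, toy chains) can be built for testing and for
#' method development.
#'
#' @param segments data.frame with columns \code{name, parent, joint, jtype,
#'   axis, loc_x, loc_y, mass, com_x, com_y, izz}. \code{jtype} is one of
#'   \code{"float"} (3-DOF planar root), \code{"rev"} or \code{"weld"}.
#' @param coordinates data.frame with columns \code{name, joint, kind,
#'   sagittal, segment} (and optionally \code{locked}).
#' @param muscles optional musculotendon table (see
#'   \code{\link{build_healthy_model}} for the packaged roster).
#' @param markers optional marker table (\code{name, segment, x, y, z}).
#' @param actuators optional ideal-actuator table (\code{name, coord,
#'   tau_max}).
#' @param name model label.
#' @return an object of class \code{msk_model}.
#' @export
msk_model <- function(segments, coordinates, muscles = NULL, markers = NULL,
                      actuators = NULL, name = "model") {
  stopifnot(is.data.frame(segments), is.data.frame(coordinates))
  if (any(segments$mass < 0)) stopf("segment masses must be >= 0")
  if (any(segments$izz < 0)) stopf("segment inertias must be >= 0")
  if (is.null(coordinates$locked)) coordinates$locked <- FALSE
  bad <- setdiff(segments$parent, c("ground", segments$name))
  if (length(bad)) stopf("unknown parent segment(s): %s", paste(bad, collapse = ", "))
  m <- structure(list(
    name = name, segments = segments, coordinates = coordinates,
    muscles = muscles, markers = markers, actuators = actuators,
    amputation = NULL
  ), class = "msk_model")
  m
}

#' Build the generic healthy lower-extremity model
#'
#' Assembles the packaged generic-adult model: 23 unlocked coordinates
#' (3 lumbar, 6 pelvis, 3 per hip, 1 per knee, 1 per ankle, 2 per foot) and
#' 92 Hill-type musculotendon units distributed symmetrically, 43 per leg plus
#' 3 lumbar-support units per side. The two foot coordinates of each side
#' (subtalar and metatarsophalangeal) can be locked with
#' \code{\link{lock_coordinates}} for sagittal-plane work.
#'
#' @return an \code{msk_model}.
#' @examples
#' m <- build_healthy_model()
#' dof_count(m)   # 23
#' mtu_count(m)   # 92
#' @export
build_healthy_model <- function() {
  segs <- og_segment_table()
  coords <- og_coordinate_table()
  one <- og_muscle_table_one_side()
  mus <- do.call(rbind, lapply(c("r", "l"), function(side) {
    d <- one
    d$base <- d$name
    d$name <- paste0(d$name, "_", side)
    d$side <- side
    d$vmax <- 10
    d$status <- "active"
    d
  }))
  rownames(mus) <- NULL
  msk_model(segs, coords, muscles = mus, markers = og_marker_table(),
            name = "healthy_23dof")
}

#' Count unlocked degrees of freedom
#' @param model an \code{msk_model}.
#' @return integer DOF count (locked coordinates contribute nothing).
#' @export
dof_count <- function(model) sum(!model$coordinates$locked)

#' Count musculotendon units in the roster
#'
#' Removed units are absent from the roster; disabled-anchored units remain
#' counted (they are present in the model but produce no force).
#' @param model an \code{msk_model}.
#' @return integer.
#' @export
mtu_count <- function(model) if (is.null(model$muscles)) 0L else nrow(model$muscles)

#' Lock coordinates at their neutral position
#'
#' Locked coordinates are fixed at zero, excluded from the DOF count and from
#' the unknown vectors of inverse kinematics and dynamics. Locking is
#' idempotent.
#'
#' @param model an \code{msk_model}.
#' @param names coordinate names to lock.
#' @return the modified model.
#' @export
lock_coordinates <- function(model, names) {
  unknown <- setdiff(names, model$coordinates$name)
  if (length(unknown)) stopf("unknown coordinate(s): %s", paste(unknown, collapse = ", "))
  model$coordinates$locked[model$coordinates$name %in% names] <- TRUE
  model
}

#' Specification of the amputation + prosthesis transform
#'
#' Bundles the geometric and inertial constants of the generic
#' osseointegrated prosthesis and the fate of the amputated-side muscles.
#' Defaults are the generic unscaled values: the femur transected to 0.247 m
#' with recomputed inertial properties (bone density 350 kg/m^3), a 0.205 m /
#' 0.35 kg titanium implant welded to the residual femur, a 0.43 m / 1.4 kg
#' tibia pylon carrying the prosthetic knee and ankle revolutes, and a 0.8 kg
#' prosthetic foot. Sixteen muscles lost to the amputation are removed and
#' eight bi-articular muscles are re-attached to the residual femur and
#' disabled.
#'
#' @param side "r" or "l".
#' @param removed,anchored anatomical muscle-name lists (numbered
#'   musculotendon units are resolved to all their units). The two lists must
#'   be disjoint.
#' @param actuator_tau_max optimal torque of the two ideal prosthesis
#'   actuators (N.m).
#' @return an object of class \code{amputation_spec}.
#' @export
amputation_spec <- function(side = "r",
                            removed = og_removed_muscles(),
                            anchored = og_anchored_muscles(),
                            actuator_tau_max = 1e6) {
  stopifnot(side %in% c("r", "l"))
  if (length(intersect(removed, anchored)))
    stopf("removed and anchored muscle lists must be disjoint")
  structure(list(
    side = side,
    femur_length = 0.247,
    implant_length = 0.205, implant_mass = 0.35,
    pylon_length = 0.43, pylon_mass = 1.4,
    foot_mass = 0.8,
    bone_density = 350,
    femur = list(mass = 4.65, com = c(0, -0.07), izz = 0.02392),
    implant = list(mass = 0.35, com = c(0, -0.133), izz = 0.0013),
    pylon = list(mass = 1.4, com = c(0, -0.213), izz = 0.03215),
    foot = list(mass = 0.8, com = c(0.0186, -0.0213), izz = 0.0025),
    removed = removed, anchored = anchored,
    actuator_tau_max = actuator_tau_max
  ), class = "amputation_spec")
}

# resolve anatomical names to musculotendon-unit rows of one side
resolve_units <- function(muscles, names, side) {
  base <- sub("[0-9]+$", "", muscles$base)
  hit <- muscles$side == side & (muscles$base %in% names | base %in% names)
  muscles$name[hit]
}

#' Transform the healthy model into the osseointegrated transfemoral model
#'
#' Applies the unilateral amputation + generic prosthesis transform: the
#' amputated-side femur is replaced by the transected femur with the
#' osseointegrated implant welded to it, a tibia pylon with prosthetic knee
#' and ankle revolute coordinates and a prosthetic foot are attached (joint
#' centres mirroring the contralateral side), the sixteen lost muscles are
#' removed from the roster, the eight bi-articular muscles are re-attached to
#' the residual femur (losing their knee moment arm) and disabled, and two
#' ideal torque actuators are created at the prosthetic knee and ankle. The
#' amputated-side foot coordinates disappear with the anatomical foot and the
#' contralateral subtalar/metatarsophalangeal coordinates are locked, giving
#' 19 unlocked DOFs and 76 musculotendon units.
#'
#' @param model a healthy \code{msk_model} from \code{\link{build_healthy_model}}.
#' @param spec an \code{\link{amputation_spec}}.
#' @return the amputee \code{msk_model} (with an \code{amputation} element
#'   recording the spec and the unit fates).
#' @export
apply_amputation <- function(model, spec = amputation_spec()) {
  side <- spec$side
  other <- if (side == "r") "l" else "r"
  sfx <- paste0("_", side)

  mus <- model$muscles
  removed_units <- resolve_units(mus, spec$removed, side)
  anchored_units <- resolve_units(mus, spec$anchored, side)
  miss <- setdiff(paste0(c(spec$removed, spec$anchored), sfx),
                  c(mus$name, sub("[0-9]+$", "", mus$name)))
  miss <- miss[!sub(sfx, "", miss) %in% sub("[0-9]+$", "", mus$base)]
  if (length(miss)) stopf("muscle name(s) not in model: %s", paste(miss, collapse = ", "))
  if (length(removed_units) == 0L) stopf("no removed units resolved")

  mus <- mus[!mus$name %in% removed_units, ]
  anch <- mus$name %in% anchored_units
  mus$status[anch] <- "disabled_anchored"
  mus$r_knee[anch] <- 0  # re-attached on the residual femur: knee not spanned
  rownames(mus) <- NULL

  segs <- model$segments
  femur <- paste0("femur", sfx)
  tibia <- paste0("tibia", sfx)
  foot <- paste0("foot", sfx)
  knee_loc <- unlist(segs[segs$name == paste0("tibia_", other),
                          c("loc_x", "loc_y")])
  ankle_loc <- unlist(segs[segs$name == paste0("foot_", other),
                           c("loc_x", "loc_y")])
  segs <- segs[!segs$name %in% c(femur, tibia, foot), ]
  hip_row <- og_segment_table()
  hip_row <- hip_row[hip_row$name == femur, ]
  add <- data.frame(
    name = c(paste0("femur_trans", sfx), paste0("osseo_pylon", sfx),
             paste0("tibia_pylon", sfx), paste0("pros_foot", sfx)),
    parent = c("pelvis", paste0("femur_trans", sfx),
               paste0("femur_trans", sfx), paste0("tibia_pylon", sfx)),
    joint = c(paste0("hip", sfx), paste0("osseo_weld", sfx),
              "pros_knee", "pros_ankle"),
    jtype = c("rev", "weld", "rev", "rev"),
    axis = c(1, 0, -1, 1),
    loc_x = c(hip_row$loc_x, 0, knee_loc[1L], ankle_loc[1L]),
    loc_y = c(hip_row$loc_y, 0, knee_loc[2L], ankle_loc[2L]),
    mass = c(spec$femur$mass, spec$implant$mass, spec$pylon$mass, spec$foot$mass),
    com_x = c(spec$femur$com[1L], spec$implant$com[1L], spec$pylon$com[1L], spec$foot$com[1L]),
    com_y = c(spec$femur$com[2L], spec$implant$com[2L], spec$pylon$com[2L], spec$foot$com[2L]),
    izz = c(spec$femur$izz, spec$implant$izz, spec$pylon$izz, spec$foot$izz)
  )
  segs <- rbind(segs, add)
  rownames(segs) <- NULL

  coords <- model$coordinates
  drop <- paste0(c("knee_angle", "ankle_angle", "subtalar_angle", "mtp_angle"), sfx)
  coords <- coords[!coords$name %in% drop, ]
  coords <- rbind(coords, data.frame(
    name = c("pros_knee", "pros_ankle"),
    joint = c("pros_knee", "pros_ankle"), kind = "rot", sagittal = TRUE,
    segment = c(paste0("tibia_pylon", sfx), paste0("pros_foot", sfx)),
    locked = FALSE))
  rownames(coords) <- NULL

  # segment re-attachment of the amputated-side coordinates' hosts and markers
  mk <- model$markers
  remap <- c(paste0("femur_trans", sfx), paste0("tibia_pylon", sfx),
             paste0("pros_foot", sfx))
  names(remap) <- c(femur, tibia, foot)
  hit <- mk$segment %in% names(remap)
  mk$segment[hit] <- remap[mk$segment[hit]]
  hitc <- coords$segment %in% names(remap)
  coords$segment[hitc] <- remap[coords$segment[hitc]]

  act <- data.frame(
    name = c("pros_knee_act", "pros_ankle_act"),
    coord = c("pros_knee", "pros_ankle"),
    tau_max = spec$actuator_tau_max)

  out <- msk_model(segs, coords, muscles = mus, markers = mk,
                   actuators = act, name = paste0("oi_tfa", sfx))
  out <- lock_coordinates(out, paste0(c("subtalar_angle", "mtp_angle"),
                                      paste0("_", other)))
  out$amputation <- list(spec = spec, removed_units = removed_units,
                         anchored_units = anchored_units)
  out
}

#' Summary counts of an amputation transform
#'
#' @param model an amputee \code{msk_model}.
#' @return list with \code{n_removed_units}, \code{n_anchored_units},
#'   \code{n_removed_muscles} and \code{n_anchored_muscles} (distinct
#'   anatomical names; the adductor magnus contributes three musculotendon
#'   units but counts as one muscle).
#' @export
amputation_summary <- function(model) {
  a <- model$amputation
  if (is.null(a)) stopf("model carries no amputation record")
  strip <- function(x) unique(sub("[0-9]+$", "", sub("_[rl]$", "", x)))
  list(n_removed_units = length(a$removed_units),
       n_anchored_units = length(a$anchored_units),
       n_removed_muscles = length(strip(a$removed_units)),
       n_anchored_muscles = length(strip(a$anchored_units)))
}

#' Combine a chain of weld-connected segments into one rigid body
#'
#' Mass is summed, the centre of mass is the mass-weighted barycentre, and
#' the sagittal inertia follows the parallel-axis theorem. The composite is
#' expressed in the frame of the first segment; each row's \code{off_x, off_y}
#' give that segment's frame position in the composite frame.
#'
#' @param segments data.frame with columns \code{mass, com_x, com_y, izz} and
#'   optionally \code{off_x, off_y} (default 0).
#' @return list with \code{mass}, \code{com} (length-2) and \code{izz}.
#' @examples
#' femur <- data.frame(mass = 4.65, com_x = 0, com_y = -0.07, izz = 0.02392)
#' implant <- data.frame(mass = 0.35, com_x = 0, com_y = -0.133, izz = 0.0013)
#' composite_welded_body(rbind(femur, implant))$mass  # 5.0
#' @export
composite_welded_body <- function(segments) {
  s <- segments
  if (is.null(s$off_x)) s$off_x <- 0
  if (is.null(s$off_y)) s$off_y <- 0
  mass <- sum(s$mass)
  if (mass == 0) return(list(mass = 0, com = c(0, 0), izz = sum(s$izz)))
  cx <- s$off_x + s$com_x
  cy <- s$off_y + s$com_y
  com <- c(sum(s$mass * cx), sum(s$mass * cy)) / mass
  d2 <- (cx - com[1L])^2 + (cy - com[2L])^2
  list(mass = mass, com = com, izz = sum(s$izz + s$mass * d2))
}

#' Total model mass
#' @param model an \code{msk_model}.
#' @return mass in kg.
#' @export
model_mass <- function(model) sum(model$segments$mass)

#' @export
print.msk_model <- function(x, ...) {
  cat(sprintf("<msk_model '%s'>\n", x$name))
  cat(sprintf("  segments: %d (total mass %.3f kg)\n",
              nrow(x$segments), model_mass(x)))
  cat(sprintf("  coordinates: %d (%d unlocked DOFs, %d sagittal-dynamic)\n",
              nrow(x$coordinates), dof_count(x),
              sum(x$coordinates$sagittal & !x$coordinates$locked)))
  if (!is.null(x$muscles)) {
    st <- table(x$muscles$status)
    cat(sprintf("  musculotendon units: %d (%s)\n", mtu_count(x),
                paste(sprintf("%s %d", names(st), st), collapse = ", ")))
  }
  if (!is.null(x$actuators))
    cat(sprintf("  ideal actuators: %s\n", paste(x$actuators$coord, collapse = ", ")))
  invisible(x)
}

#' Names of the sagittal dynamic coordinates
#'
#' The unlocked sagittal-plane coordinates carried by the dynamic engine,
#' in coordinate-table order (the q vector of the containers uses this set;
#' the dynamic tree may order them differently and matches by name).
#'
#' @param model an \code{msk_model}.
#' @return character vector.
#' @export
dynamic_coords <- function(model) {
  co <- model$coordinates
  co$name[co$sagittal & !co$locked]
}
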