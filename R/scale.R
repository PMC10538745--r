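# Subject scaling from a static trial: per-segment scale factors from
# marker-pair distances, mass redistribution to the subject's total mass,
# and a virtual-vs-experimental marker RMSE report against the ~1 cm
# guideline.

# marker pairs measuring each segment's length (virtual distances taken at
# the neutral pose); 'both' entries apply one factor to both sides
scale_pair_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
target    m1    m2
pelvis    RASI  LASI
torso     C7    SACR
femur_r   RASI  RKNE
tibia_r   RKNE  RANK
foot_r    RHEE  RTOE
femur_l   LASI  LKNE
tibia_l   LKNE  LANK
foot_l    LHEE  LTOE
")
}

#' Default static (scaling) marker weights
#'
#' Bony-landmark markers on the lateral knees and ankles carry weight 5,
#' upper-body markers weight 1, everything else an intermediate 2.5.
#'
#' @param model an \code{msk_model}.
#' @param bony_weight,upper_weight the two printed weight levels.
#' @return named numeric vector.
#' @export
scale_default_weights <- function(model, bony_weight = 5, upper_weight = 1) {
  nm <- model$markers$name
  w <- rep((bony_weight + upper_weight) / 2, length(nm))
  names(w) <- nm
  w[grepl("(KNE|ANK)$", nm)] <- bony_weight
  upper <- model$markers$segment == "torso"
  w[nm[upper]] <- upper_weight
  w
}

#' Scale a model to a subject from a static trial
#'
#' Computes one scale factor per segment as the ratio of the experimental
#' marker-pair distance (averaged over the static frames) to the model's
#' virtual pair distance at the neutral pose; applies the factors to joint
#' locations, centres of mass, marker offsets, segment inertias (factor
#' squared) and musculotendon lengths (leg muscles by the mean of their
#' side's femur/tibia factors, lumbar muscles by the torso factor). When a
#' subject mass is given, segment masses are rescaled proportionally to
#' preserve it. A static pose is then fitted with the static weights and the
#' virtual-vs-experimental marker RMSE reported.
#'
#' @param model an \code{msk_model}.
#' @param static_trial a \code{\link{marker_trajectories}} of the static
#'   standing pose.
#' @param weights static marker weights (default
#'   \code{\link{scale_default_weights}}).
#' @param subject_mass optional subject mass (kg).
#' @return list with \code{model} (scaled) and \code{scale_set} (factors,
#'   per-marker RMSE, guideline flag).
#' @export
scale_model <- function(model, static_trial, weights = NULL,
                        subject_mass = NULL) {
  mk_avg <- apply(static_trial$positions, c(2L, 3L), mean)
  rownames(mk_avg) <- static_trial$marker_names
  fk0 <- forward_kinematics(model, numeric(length(dynamic_coords(model))))
  virt <- fk0$markers

  pairs <- scale_pair_table()
  factors <- setNames(rep(1, nrow(model$segments)), model$segments$name)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (!all(c(p$m1, p$m2) %in% rownames(mk_avg)) ||
        !all(c(p$m1, p$m2) %in% rownames(virt))) next
    d_exp <- sqrt(sum((mk_avg[p$m1, ] - mk_avg[p$m2, ])^2))
    d_mod <- sqrt(sum((virt[p$m1, ] - virt[p$m2, ])^2))
    if (d_mod < 1e-9) stopf("degenerate virtual pair distance for '%s'", p$target)
    if (d_exp < 1e-9) stopf("degenerate experimental pair distance for '%s'", p$target)
    tg <- p$target
    if (!tg %in% names(factors)) {
      # amputee models: femur_r -> femur_trans_r, tibia_r -> tibia_pylon_r, ...
      side <- substring(tg, nchar(tg))
      base <- sub("_[rl]$", "", tg)
      alt <- paste0(c(femur = "femur_trans", tibia = "tibia_pylon",
                      foot = "pros_foot")[base], "_", side)
      if (is.na(alt) || !alt %in% names(factors)) next
      tg <- alt
    }
    factors[tg] <- d_exp / d_mod
  }
  # welded/prosthetic attachments inherit their parent chain factor
  segs <- model$segments
  for (i in seq_len(nrow(segs))) {
    nmv <- segs$name[i]
    if (factors[nmv] == 1 && segs$parent[i] %in% names(factors) &&
        grepl("pylon|pros", nmv))
      factors[nmv] <- factors[segs$parent[i]]
  }

  scaled <- model
  for (i in seq_len(nrow(scaled$segments))) {
    s <- scaled$segments$name[i]
    f_own <- factors[s]
    # joint location lives in the parent frame
    p <- scaled$segments$parent[i]
    f_par <- if (p %in% names(factors)) factors[p] else 1
    scaled$segments$loc_x[i] <- scaled$segments$loc_x[i] * f_par
    scaled$segments$loc_y[i] <- scaled$segments$loc_y[i] * f_par
    scaled$segments$com_x[i] <- scaled$segments$com_x[i] * f_own
    scaled$segments$com_y[i] <- scaled$segments$com_y[i] * f_own
    scaled$segments$izz[i] <- scaled$segments$izz[i] * f_own^2
  }
  mhit <- match(scaled$markers$segment, names(factors))
  fmk <- ifelse(is.na(mhit), 1, factors[ifelse(is.na(mhit), 1L, mhit)])
  scaled$markers$x <- scaled$markers$x * fmk
  scaled$markers$y <- scaled$markers$y * fmk
  scaled$markers$z <- scaled$markers$z * fmk

  if (!is.null(scaled$muscles)) {
    for (side in c("r", "l")) {
      fem <- grep(paste0("^femur.*_", side, "$"), names(factors), value = TRUE)[1L]
      tib <- grep(paste0("^(tibia|tibia_pylon).*_", side, "$"), names(factors), value = TRUE)[1L]
      f_leg <- mean(c(factors[fem], factors[tib]), na.rm = TRUE)
      sel <- scaled$muscles$side == side & scaled$muscles$group == "leg"
      for (col in c("lopt", "lslack", "r_hip", "r_knee", "r_ankle"))
        scaled$muscles[[col]][sel] <- scaled$muscles[[col]][sel] * f_leg
      sel_l <- scaled$muscles$side == side & scaled$muscles$group == "lumbar"
      for (col in c("lopt", "lslack", "r_lumbar"))
        scaled$muscles[[col]][sel_l] <- scaled$muscles[[col]][sel_l] * factors["torso"]
    }
  }

  if (!is.null(subject_mass)) {
    ratio <- subject_mass / model_mass(scaled)
    scaled$segments$mass <- scaled$segments$mass * ratio
    scaled$segments$izz <- scaled$segments$izz * ratio
  }

  if (is.null(weights)) weights <- scale_default_weights(model)
  fit <- solve_ik_frame(scaled, mk_avg, weights = weights)
  list(model = scaled,
       scale_set = list(factors = factors, rmse = fit$rmse,
                        max_error = fit$max_error,
                        errors = fit$errors,
                        within_guideline = fit$rmse < 0.02))
}
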