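# Packaged generic-adult model data.
#
# Segment masses, centres of mass and sagittal inertias are patterned on the
# standard 23-DOF lower-extremity gait model distributed with common
# musculoskeletal simulation software; muscle Hill parameters and sagittal
# moment arms are generic adult values assembled from the same tradition.
# All quantities are SI (m, kg, s, N, N.m, rad). The sagittal plane is x-y
# (x forward, y up); z points to the subject's right and is kinematically
# inert in this planar engine.

# ---- skeleton -------------------------------------------------------------

og_segment_table <- function() {
  # loc_*: joint location in the parent frame; com_*: in the segment frame
  df <- read.table(header = TRUE, text = "
name     parent   joint        jtype    axis loc_x    loc_y    mass     com_x   com_y   izz
pelvis   ground   ground_pelvis float   -1   0        0        11.777  -0.0707  0       0.0973
torso    pelvis   back          rev      1  -0.1007   0.0815   34.2366 -0.03    0.32    1.4745
femur_r  pelvis   hip_r         rev      1  -0.0707  -0.0661    9.3014  0      -0.17    0.1337
tibia_r  femur_r  knee_r        rev     -1   0       -0.396     3.7075  0      -0.1867  0.0511
foot_r   tibia_r  ankle_r       rev      1   0       -0.43      1.5666  0.09   -0.035   0.0087
femur_l  pelvis   hip_l         rev      1  -0.0707  -0.0661    9.3014  0      -0.17    0.1337
tibia_l  femur_l  knee_l        rev     -1   0       -0.396     3.7075  0      -0.1867  0.0511
foot_l   tibia_l  ankle_l       rev      1   0       -0.43      1.5666  0.09   -0.035   0.0087
")
  df
}

# coordinate roster for the healthy model; 'sagittal' marks the coordinates
# carried by the planar dynamic engine, the others are kinematic placeholders
og_coordinate_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name               joint         kind  sagittal segment
pelvis_tx          ground_pelvis trans TRUE     pelvis
pelvis_ty          ground_pelvis trans TRUE     pelvis
pelvis_tz          ground_pelvis trans FALSE    pelvis
pelvis_tilt        ground_pelvis rot   TRUE     pelvis
pelvis_list        ground_pelvis rot   FALSE    pelvis
pelvis_rotation    ground_pelvis rot   FALSE    pelvis
lumbar_extension   back          rot   TRUE     torso
lumbar_bending     back          rot   FALSE    torso
lumbar_rotation    back          rot   FALSE    torso
hip_flexion_r      hip_r         rot   TRUE     femur_r
hip_adduction_r    hip_r         rot   FALSE    femur_r
hip_rotation_r     hip_r         rot   FALSE    femur_r
knee_angle_r       knee_r        rot   TRUE     tibia_r
ankle_angle_r      ankle_r       rot   TRUE     foot_r
subtalar_angle_r   subtalar_r    rot   FALSE    foot_r
mtp_angle_r        mtp_r         rot   FALSE    foot_r
hip_flexion_l      hip_l         rot   TRUE     femur_l
hip_adduction_l    hip_l         rot   FALSE    femur_l
hip_rotation_l     hip_l         rot   FALSE    femur_l
knee_angle_l       knee_l        rot   TRUE     tibia_l
ankle_angle_l      ankle_l       rot   TRUE     foot_l
subtalar_angle_l   subtalar_l    rot   FALSE    foot_l
mtp_angle_l        mtp_l         rot   FALSE    foot_l
")
}

# ---- marker set (28 markers, plug-in-gait style naming) --------------------

og_marker_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name  segment  x       y       z
RASI  pelvis   0.02    0.03    0.128
LASI  pelvis   0.02    0.03   -0.128
RPSI  pelvis  -0.155   0.035   0.045
LPSI  pelvis  -0.155   0.035  -0.045
SACR  pelvis  -0.17    0.03    0
RTHI  femur_r  0.02   -0.20    0.06
RKNE  femur_r  0      -0.396   0.055
RTIB  tibia_r  0.01   -0.20    0.05
RANK  tibia_r  0      -0.43    0.045
RHEE  foot_r  -0.03   -0.045   0
RTOE  foot_r   0.19   -0.05    0
LTHI  femur_l  0.02   -0.20   -0.06
LKNE  femur_l  0      -0.396  -0.055
LTIB  tibia_l  0.01   -0.20   -0.05
LANK  tibia_l  0      -0.43   -0.045
LHEE  foot_l  -0.03   -0.045   0
LTOE  foot_l   0.19   -0.05    0
C7    torso   -0.06    0.44    0
T10   torso   -0.08    0.25    0
CLAV  torso    0.04    0.42    0
STRN  torso    0.06    0.31    0
RBAK  torso   -0.09    0.38    0.09
RSHO  torso   -0.01    0.43    0.19
LSHO  torso   -0.01    0.43   -0.19
RFHD  torso    0.07    0.61    0.065
LFHD  torso    0.07    0.61   -0.065
RBHD  torso   -0.08    0.62    0.065
LBHD  torso   -0.08    0.62   -0.065
")
}

# ---- musculotendon roster (46 per side -> 92) ------------------------------
#
# Columns: Hill parameters (F0 N, lopt m, lslack m, vmax in optimal lengths/s)
# and constant sagittal moment arms (m) about hip flexion, knee flexion,
# ankle dorsiflexion and lumbar extension (positive arm = positive torque for
# the named positive direction). Muscles whose main action is out of the
# sagittal plane carry zero (or small residual) sagittal arms but stay in the
# roster and in every cost term.
og_muscle_table_one_side <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name      group  F0    lopt   lslack r_hip  r_knee r_ankle r_lumbar
glut_med1 leg    819   0.0535 0.078  -0.005  0      0       0
glut_med2 leg    573   0.0845 0.053  -0.010  0      0       0
glut_med3 leg    653   0.0646 0.053  -0.015  0      0       0
glut_min1 leg    270   0.068  0.016  -0.005  0      0       0
glut_min2 leg    285   0.056  0.026  -0.010  0      0       0
glut_min3 leg    323   0.038  0.051  -0.012  0      0       0
semimem   leg    1288  0.080  0.359  -0.055  0.035  0       0
semiten   leg    410   0.201  0.262  -0.050  0.040  0       0
bifemlh   leg    896   0.109  0.341  -0.055  0.035  0       0
bifemsh   leg    804   0.173  0.089   0      0.035  0       0
sar       leg    156   0.520  0.040   0.035  0.010  0       0
add_long  leg    627   0.138  0.110  -0.008  0      0       0
add_brev  leg    429   0.133  0.020   0.005  0      0       0
add_mag1  leg    381   0.087  0.060  -0.020  0      0       0
add_mag2  leg    381   0.121  0.120  -0.025  0      0       0
add_mag3  leg    381   0.131  0.260  -0.030  0      0       0
tfl       leg    233   0.095  0.425   0.030  0      0       0
pect      leg    177   0.133  0.001   0.020  0      0       0
grac      leg    162   0.352  0.140   0.010  0.015  0       0
glut_max1 leg    573   0.142  0.125  -0.050  0      0       0
glut_max2 leg    819   0.147  0.127  -0.060  0      0       0
glut_max3 leg    552   0.144  0.145  -0.055  0      0       0
iliacus   leg    1073  0.100  0.100   0.043  0      0       0
psoas     leg    1113  0.104  0.130   0.042  0      0       0
quad_fem  leg    381   0.054  0.024  -0.010  0      0       0
gem       leg    164   0.024  0.039   0      0      0       0
peri      leg    444   0.026  0.115  -0.005  0      0       0
rect_fem  leg    1169  0.084  0.346   0.040 -0.045  0       0
vas_med   leg    1294  0.089  0.126   0     -0.045  0       0
vas_int   leg    1365  0.087  0.136   0     -0.045  0       0
vas_lat   leg    1871  0.084  0.157   0     -0.048  0       0
med_gas   leg    1558  0.060  0.390   0      0.020 -0.048   0
lat_gas   leg    683   0.064  0.385   0      0.020 -0.048   0
soleus    leg    3549  0.050  0.250   0      0     -0.048   0
tib_post  leg    1270  0.031  0.310   0      0     -0.012   0
flex_dig  leg    310   0.034  0.400   0      0     -0.018   0
flex_hal  leg    322   0.043  0.380   0      0     -0.020   0
tib_ant   leg    905   0.098  0.223   0      0      0.040   0
per_brev  leg    435   0.050  0.161   0      0     -0.010   0
per_long  leg    754   0.049  0.345   0      0     -0.012   0
per_tert  leg    90    0.079  0.100   0      0      0.025   0
ext_dig   leg    512   0.102  0.345   0      0      0.035   0
ext_hal   leg    162   0.111  0.305   0      0      0.033   0
ercspn    lumbar 2500  0.120  0.030   0      0      0       0.055
intobl    lumbar 900   0.100  0.100   0      0      0      -0.040
extobl    lumbar 900   0.120  0.140   0      0      0      -0.045
")
}

# amputated-side muscle fate lists (anatomical names; numbered musculotendon
# units such as add_mag1/2/3 are resolved to all their units)
og_removed_muscles <- function() c(
  "vas_med", "vas_int", "vas_lat", "med_gas", "lat_gas", "soleus",
  "tib_post", "flex_dig", "flex_hal", "tib_ant", "per_brev", "per_long",
  "per_tert", "ext_dig", "ext_hal", "bifemsh"
)

og_anchored_muscles <- function() c(
  "semimem", "semiten", "bifemlh", "sar", "add_mag", "tfl", "grac", "rect_fem"
)

# functional muscle groups for post-processing; membership is packaged data
# and editable by the user
og_muscle_groups <- function() list(
  hip_flexors    = c("psoas", "iliacus", "pect", "rect_fem", "sar", "tfl",
                     "grac", "add_brev"),
  hip_extensors  = c("glut_max1", "glut_max2", "glut_max3", "glut_med1",
                     "glut_med2", "glut_med3", "glut_min1", "glut_min2",
                     "glut_min3", "add_long", "add_mag1", "add_mag2",
                     "add_mag3", "semimem", "semiten", "bifemlh"),
  knee_extensors = c("vas_med", "vas_int", "vas_lat", "rect_fem"),
  knee_flexors   = c("semimem", "semiten", "bifemlh", "bifemsh", "sar",
                     "grac", "med_gas", "lat_gas"),
  plantarflexors = c("soleus", "tib_post", "med_gas", "lat_gas", "per_brev",
                     "per_long", "flex_dig", "flex_hal"),
  dorsiflexors   = c("tib_ant", "ext_dig", "ext_hal", "per_tert")
)

# ---- synthetic gait waveforms ---------------------------------------------
#
# Truncated Fourier series (6 harmonics) over one gait cycle, fitted once to
# canonical sagittal gait shapes and frozen here as synthetic design data (no
# figure digitisation). Values in degrees except the pelvis translations (m).
# Layout: c(a0, a1..a6, b1..b6) for a0 + sum ak cos(2 pi k s) + bk sin(.).
og_waveforms <- function() list(
  hip_healthy   = c(11.29924, 19.20219, -2.29293, -0.24205, 0.01949, 0.03589, -0.01427, -4.44693, -1.99387, 0.16863, 0.14770, -0.02158, -0.01601),
  knee_healthy  = c(22.59056, -2.76071, -12.44711, 1.17224, 0.14489, -0.44593, -0.23994, -18.66636, 8.94117, 4.32875, -0.54899, -0.39798, 0.10393),
  ankle_healthy = c(-0.09253, -0.84495, 0.39340, -0.10092, 0.50458, 0.02922, 0.06891, 4.48784, -7.32837, 1.56555, -0.65808, 0.08697, -0.05596),
  hip_amp       = c(10.18561, 16.24586, -1.64027, 0.21123, -0.02855, 0.03224, -0.00823, -5.37598, -0.71136, 0.01220, 0.06423, 0.00462, -0.01081),
  pros_knee     = c(9.54285, 2.17391, -9.60136, -2.76276, 2.80055, 0.48855, -0.34989, -12.90708, -3.19650, 5.87309, 1.53643, -0.98325, 0.01273),
  pros_ankle    = c(-0.09615, -0.11637, 0.39238, -0.07523, -0.12717, 0.02639, -0.00687, 5.33220, -2.56452, 0.20372, 0.02336, 0.03134, -0.00594),
  ankle_contra  = c(-0.68948, -0.73744, 0.82848, -0.07761, 0.51450, 0.03976, 0.07451, 5.41936, -7.45950, 1.53045, -0.67466, 0.09100, -0.05684),
  pelvis_tilt   = c(3, 0, 1.5, 0, 0, 0, 0, 0, 0.5, 0, 0, 0, 0),
  lumbar_ext    = c(-3, 0, 1.0, 0, 0, 0, 0, 0, 0.5, 0, 0, 0, 0),
  pelvis_tx_m   = c(0, -0.04, 0, 0, 0, 0, 0, -0.01, 0, 0, 0, 0, 0),
  pelvis_ty_m   = c(0.93, 0, 0.012, 0, 0, 0, 0, 0, 0.004, 0, 0, 0, 0)
)

# evaluate a waveform and its first two analytic derivatives at cycle
# fraction s (may be a vector), given the cycle duration (s)
eval_waveform <- function(cf, s, cycle, deriv = 0L) {
  K <- (length(cf) - 1L) / 2L
  a <- cf[2L:(K + 1L)]; b <- cf[(K + 2L):(2L * K + 1L)]
  out <- if (deriv == 0L) rep(cf[1L], length(s)) else numeric(length(s))
  for (k in seq_len(K)) {
    w <- 2 * pi * k / cycle
    th <- 2 * pi * k * s
    out <- out + switch(as.character(deriv),
      "0" = a[k] * cos(th) + b[k] * sin(th),
      "1" = w * (-a[k] * sin(th) + b[k] * cos(th)),
      "2" = -w^2 * (a[k] * cos(th) + b[k] * sin(th)))
  }
  out
}
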