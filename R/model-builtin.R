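# The built-in thoracoscapular shoulder model fixture.
#
# Muscle architecture (F_max, optimal fiber length, tendon slack length,
# pennation) carries the published 33-actuator parameter set. Attachment
# coordinates, wrap geometry and segment properties are AUTHORED
# approximations chosen so that each muscle's line of action produces
# qualitatively correct moment signs (e.g. superior trapezius elevates and
# upward-rotates the scapula); they are a testing fixture, not anatomical
# ground truth. Users wanting anatomical fidelity should import a curated
# model file with read_model().

# -- 33-row musculotendon parameter table ------------------------------------
# columns: name, group, f_max (N), l_opt (m), l_ts (m), pennation (deg),
# source_bundles (aggregated anatomical bundles).
builtin_muscle_table <- function() {
  tab <- rbind(
    c("Trapezius.ScapulaSuperior",    "Scapula superior", 1043,   0.1127, 0.027, 0,  "1-6"),
    c("Trapezius.ScapulaMiddle",      "Scapula middle",   470.4,  0.0832, 0.032, 0,  "7-9"),
    c("Trapezius.ScapulaInferior",    "Scapula inferior", 414.4,  0.1264, 0.035, 0,  "10-12"),
    c("Trapezius.Clavicle",           "Clavicle",         201.6,  0.1116, 0.027, 0,  "C1-C2"),
    c("SerratusAnterior.Superior",    "Superior",         387.8,  0.0945, 0.000, 0,  "9-12"),
    c("SerratusAnterior.Middle",      "Middle",           508,    0.1538, 0.012, 0,  "5-8"),
    c("SerratusAnterior.Inferior",    "Inferior",         430,    0.1587, 0.000, 0,  "1-4"),
    c("Rhomboideus.Superior",         "Superior",         200.2,  0.0986, 0.015, 0,  "1-2"),
    c("Rhomboideus.Inferior",         "Inferior",         407.4,  0.1152, 0.028, 0,  "3-4"),
    c("LevatorScapulae",              "",                 280,    0.1578, 0.019, 0,  "All"),
    c("Coracobrachialis",             "",                 648.2,  0.0683, 0.104, 0,  "All"),
    c("Deltoideus.Anterior",          "Anterior",         707.7,  0.0940, 0.088, 5,  "C1-C4"),
    c("Deltoideus.Middle",            "Middle",           2597.8, 0.0748, 0.064, 5,  "4-11"),
    c("Deltoideus.Posterior",         "Posterior",        1324.4, 0.0949, 0.076, 5,  "1-3"),
    c("LatissimusDorsi.Superior",     "Superior",         201.6,  0.2109, 0.081, 0,  "1-2"),
    c("LatissimusDorsi.Middle",       "Middle",           315,    0.2656, 0.095, 0,  "3-4"),
    c("LatissimusDorsi.Inferior",     "Inferior",         270.2,  0.3062, 0.062, 0,  "5-6"),
    c("PectoralisMajor.Clavicle",     "Clavicle",         408.8,  0.1087, 0.014, 0,  "C1-C2"),
    c("PectoralisMajor.ThoraxMiddle", "Thorax middle",    683.2,  0.1500, 0.026, 0,  "4-6"),
    c("PectoralisMajor.ThoraxInferior","Thorax inferior", 571.2,  0.1830, 0.043, 0,  "1-3"),
    c("TeresMajor",                   "",                 851.2,  0.1410, 0.006, 0,  "All"),
    c("Infraspinatus.Superior",       "Superior",         967.4,  0.0698, 0.050, 0,  "4-6"),
    c("Infraspinatus.Inferior",       "Inferior",         1037.4, 0.0677, 0.084, 0,  "1-3"),
    c("PectoralisMinor",              "",                 429.8,  0.1183, 0.032, 0,  "All"),
    c("TeresMinor",                   "",                 695.8,  0.0550, 0.051, 0,  "All"),
    c("Subscapularis.Superior",       "Superior",         540.4,  0.0676, 0.059, 5,  "1-3"),
    c("Subscapularis.Middle",         "Middle",           609,    0.0744, 0.055, 5,  "4-5,10"),
    c("Subscapularis.Inferior",       "Inferior",         854,    0.0721, 0.059, 0,  "6-9,11"),
    c("Supraspinatus.Anterior",       "Anterior",         543.2,  0.0554, 0.031, 0,  "3-4"),
    c("Supraspinatus.Posterior",      "Posterior",        326.2,  0.0591, 0.025, 0,  "1-2"),
    c("TricepsLong",                  "",                 1580.6, 0.0969, 0.241, 10, "All"),
    c("Biceps.Long",                  "Long",             485.8,  0.1412, 0.257, 0,  "All"),
    c("Biceps.Brevis",                "Brevis",           693,    0.1264, 0.212, 0,  "All"))
  data.frame(name = tab[, 1], group = tab[, 2],
             f_max = as.numeric(tab[, 3]), l_opt = as.numeric(tab[, 4]),
             l_ts = as.numeric(tab[, 5]), pennation = as.numeric(tab[, 6]),
             source_bundles = tab[, 7], stringsAsFactors = FALSE)
}

# Reference-pose (all coordinates at default) world positions used to author
# the fixture. Ground/thorax frame: x anterior, y superior, z to the
# subject's right; origin mid-thorax. Units m, sized to a 1.62 m subject.
.fixture_anatomy <- function() {
  list(
    st_center = c(0, 0.04, 0),
    st_radii  = c(0.10, 0.21, 0.12),
    st_outward = c(-0.75, 0.15, 0.65),   # contact-point direction at q = 0
    sc_joint  = c(0.05, 0.17, 0.015),    # sternoclavicular joint
    gh_center = c(-0.04, 0.16, 0.17),    # glenohumeral joint centre
    elbow     = c(-0.035, -0.135, 0.18),
    hand      = c(0.01, -0.43, 0.185),
    landmarks = list(
      C7 = c(-0.075, 0.21, 0),  T8 = c(-0.095, -0.01, 0),
      IJ = c(0.055, 0.18, 0),   PX = c(0.09, 0.03, 0),
      TS = c(-0.095, 0.155, 0.035), AI = c(-0.105, 0.015, 0.07),
      AA = c(-0.065, 0.185, 0.175), AC = c(-0.03, 0.195, 0.155),
      EL = c(-0.035, -0.135, 0.21), EM = c(-0.035, -0.135, 0.15),
      RS = c(0.0, -0.37, 0.20),  US = c(0.0, -0.37, 0.165))
  )
}

# Authored muscle attachments: world coordinates at the reference pose, as
# list(body = point) entries ordered origin -> insertion; `wraps` maps
# segment index to wrap-surface name.
.fixture_muscle_geometry <- function() {
  list(
    Trapezius.ScapulaSuperior = list(points = list(
      thorax = c(-0.07, 0.27, 0.01), scapula = c(-0.06, 0.185, 0.16))),
    Trapezius.ScapulaMiddle = list(points = list(
      thorax = c(-0.095, 0.105, 0), scapula = c(-0.085, 0.165, 0.10))),
    Trapezius.ScapulaInferior = list(points = list(
      thorax = c(-0.095, -0.005, 0), scapula = c(-0.09, 0.15, 0.045))),
    Trapezius.Clavicle = list(points = list(
      thorax = c(-0.06, 0.30, 0.0), clavicle = c(-0.01, 0.19, 0.125))),
    SerratusAnterior.Superior = list(points = list(
      thorax = c(-0.02, 0.15, 0.095), scapula = c(-0.088, 0.135, 0.06)),
      wraps = list("1" = "thorax_wrap")),
    SerratusAnterior.Middle = list(points = list(
      thorax = c(0.055, 0.06, 0.095), scapula = c(-0.095, 0.095, 0.05)),
      wraps = list("1" = "thorax_wrap")),
    SerratusAnterior.Inferior = list(points = list(
      thorax = c(0.05, -0.02, 0.095), scapula = c(-0.105, 0.015, 0.07)),
      wraps = list("1" = "thorax_wrap")),
    Rhomboideus.Superior = list(points = list(
      thorax = c(-0.08, 0.27, 0), scapula = c(-0.095, 0.155, 0.035))),
    Rhomboideus.Inferior = list(points = list(
      thorax = c(-0.095, 0.10, 0), scapula = c(-0.103, 0.025, 0.068))),
    LevatorScapulae = list(points = list(
      thorax = c(-0.04, 0.30, 0.035), scapula = c(-0.09, 0.16, 0.04))),
    Coracobrachialis = list(points = list(
      scapula = c(0.005, 0.165, 0.115), humerus = c(-0.033, 0.02, 0.165))),
    Deltoideus.Anterior = list(points = list(
      clavicle = c(-0.005, 0.19, 0.135), humerus = c(-0.025, 0.045, 0.195)),
      wraps = list("1" = "gh_wrap")),
    Deltoideus.Middle = list(points = list(
      scapula = c(-0.055, 0.19, 0.17), humerus = c(-0.025, 0.045, 0.195)),
      wraps = list("1" = "gh_wrap")),
    Deltoideus.Posterior = list(points = list(
      scapula = c(-0.075, 0.175, 0.115), humerus = c(-0.025, 0.045, 0.195)),
      wraps = list("1" = "gh_wrap")),
    LatissimusDorsi.Superior = list(points = list(
      thorax = c(-0.095, 0.01, 0), thorax2 = c(-0.05, 0.0, 0.10),
      humerus = c(-0.015, 0.09, 0.165))),
    LatissimusDorsi.Middle = list(points = list(
      thorax = c(-0.09, -0.12, 0), thorax2 = c(-0.045, -0.06, 0.105),
      humerus = c(-0.015, 0.09, 0.165))),
    LatissimusDorsi.Inferior = list(points = list(
      thorax = c(-0.075, -0.22, 0.01), thorax2 = c(-0.04, -0.10, 0.10),
      humerus = c(-0.015, 0.09, 0.165))),
    PectoralisMajor.Clavicle = list(points = list(
      clavicle = c(0.045, 0.175, 0.045), humerus = c(0.0, 0.12, 0.17))),
    PectoralisMajor.ThoraxMiddle = list(points = list(
      thorax = c(0.085, 0.10, 0.01), thorax2 = c(0.05, 0.09, 0.10),
      humerus = c(-0.022, 0.148, 0.17))),
    PectoralisMajor.ThoraxInferior = list(points = list(
      thorax = c(0.085, 0.0, 0.015), thorax2 = c(0.05, 0.04, 0.10),
      humerus = c(0.0, 0.12, 0.17))),
    TeresMajor = list(points = list(
      scapula = c(-0.10, 0.025, 0.08), humerus = c(-0.01, 0.105, 0.155))),
    Infraspinatus.Superior = list(points = list(
      scapula = c(-0.085, 0.125, 0.075), humerus = c(-0.045, 0.155, 0.185))),
    Infraspinatus.Inferior = list(points = list(
      scapula = c(-0.095, 0.07, 0.065), humerus = c(-0.045, 0.155, 0.185))),
    PectoralisMinor = list(points = list(
      thorax = c(0.07, 0.05, 0.06), scapula = c(0.005, 0.165, 0.115))),
    TeresMinor = list(points = list(
      scapula = c(-0.08, 0.08, 0.11), humerus = c(-0.045, 0.15, 0.185))),
    Subscapularis.Superior = list(points = list(
      scapula = c(-0.075, 0.135, 0.065), humerus = c(-0.005, 0.155, 0.145))),
    Subscapularis.Middle = list(points = list(
      scapula = c(-0.085, 0.105, 0.07), humerus = c(-0.005, 0.15, 0.145))),
    Subscapularis.Inferior = list(points = list(
      scapula = c(-0.09, 0.06, 0.075), humerus = c(-0.005, 0.15, 0.145))),
    Supraspinatus.Anterior = list(points = list(
      scapula = c(-0.06, 0.17, 0.09), humerus = c(-0.025, 0.185, 0.180)),
      wraps = list("1" = "gh_wrap")),
    Supraspinatus.Posterior = list(points = list(
      scapula = c(-0.06, 0.168, 0.09), humerus = c(-0.03, 0.18, 0.186)),
      wraps = list("1" = "gh_wrap")),
    TricepsLong = list(points = list(
      scapula = c(-0.05, 0.14, 0.165), forearm_hand = c(-0.07, -0.16, 0.18))),
    Biceps.Long = list(points = list(
      scapula = c(-0.035, 0.17, 0.16), forearm_hand = c(0.015, -0.175, 0.19))),
    Biceps.Brevis = list(points = list(
      scapula = c(0.005, 0.165, 0.115), forearm_hand = c(0.015, -0.175, 0.19)))
  )
}

#' Built-in thoracoscapular shoulder model
#'
#' Returns the package's fixture model: thorax (root, welded to ground),
#' clavicle (welded to the thorax in this fixture), scapula on a
#' 4-degree-of-freedom scapulothoracic ellipsoid joint, humerus on a
#' ball-and-socket glenohumeral joint, and a lumped forearm+hand segment on
#' an elbow hinge. Thirty-three Hill-type musculotendon actuators carry the
#' published architecture parameters; attachment and wrapping geometry is an
#' authored approximation (see the package vignette). Twelve ISB-style
#' markers (C7, T8, IJ, PX, TS, AI, AA, AC, EL, EM, RS, US) with equal
#' weights support marker-based inverse kinematics.
#'
#' @param hand_mass point mass in kg welded at the hand (0 or 2 in the study
#'   tasks).
#' @param wrap_tilt tilt (rad) of the thorax muscle-wrapping ellipsoid,
#'   rotating its top toward the sternum so the serratus anterior path stays
#'   well-defined over the scapular range of motion.
#' @return A [shoulder_model()].
#' @examples
#' m <- builtin_thoracoscapular_model()
#' length(m$muscles) # 33
#' m$muscles[["Deltoideus.Middle"]]$params$f_max # 2597.8
#' @export
builtin_thoracoscapular_model <- function(hand_mass = 0, wrap_tilt = 0.15) {
  an <- .fixture_anatomy()

  # scapulothoracic joint frame in the thorax
  z_ell <- normalize3(an$st_outward)
  y_ell <- normalize3(c(0, 1, 0) - sum(c(0, 1, 0) * z_ell) * z_ell)
  x_ell <- cross3(y_ell, z_ell)
  R_tilt <- cbind(x_ell, y_ell, z_ell)
  st_offset <- make_transform(R_tilt, an$st_center)

  # reference body frames (world, all q = 0)
  T_thorax <- diag(4)
  T_clav <- make_transform(diag(3), an$sc_joint)
  T_scap <- st_offset %*% scapula_transform(an$st_radii, c(0, 0, 0, 0))
  T_hum <- make_transform(diag(3), an$gh_center)
  T_fore <- make_transform(diag(3), an$elbow)
  ref <- list(thorax = T_thorax, thorax2 = T_thorax, clavicle = T_clav,
              scapula = T_scap, humerus = T_hum, forearm_hand = T_fore)
  to_local <- function(body, p_world)
    transform_point(transform_inverse(ref[[body]]), p_world)

  rod_inertia <- function(m, len, axis = 2) {
    I <- rep(m * len^2 / 12, 3); I[axis] <- m * len^2 / 600
    diag(I)
  }
  com_h <- an$gh_center + 0.45 * (an$elbow - an$gh_center)
  com_f <- an$elbow + 0.42 * (an$hand - an$elbow)
  bodies <- list(
    thorax = body_segment("thorax", 33.0, com = c(0, 0.05, 0),
                          inertia = diag(c(1.3, 0.6, 1.3))),
    clavicle = body_segment("clavicle", 0.2,
                            com = to_local("clavicle", (an$sc_joint + an$landmarks$AC) / 2),
                            inertia = diag(3) * 2e-4),
    scapula = body_segment("scapula", 0.7,
                           com = to_local("scapula", c(-0.085, 0.10, 0.09)),
                           inertia = diag(3) * 1.2e-3),
    humerus = body_segment("humerus", 1.46,
                           com = to_local("humerus", com_h),
                           inertia = rod_inertia(1.46, 0.295)),
    forearm_hand = body_segment("forearm_hand", 1.15,
                                com = to_local("forearm_hand", com_f),
                                inertia = rod_inertia(1.15, 0.30))
  )

  coords <- list(
    scap_abduction  = model_coordinate("scap_abduction", 0, c(-0.7, 0.9)),
    scap_elevation  = model_coordinate("scap_elevation", 0, c(-0.5, 0.7)),
    scap_upward_rot = model_coordinate("scap_upward_rot", 0, c(-1.2, 1.2)),
    scap_winging    = model_coordinate("scap_winging", 0, c(-0.7, 0.7)),
    gh_plane        = model_coordinate("gh_plane", 0, c(-2.0, 2.0)),
    gh_elev         = model_coordinate("gh_elev", 0, c(-0.35, 2.4)),
    gh_rot          = model_coordinate("gh_rot", 0, c(-1.6, 1.6)),
    elbow_flexion   = model_coordinate("elbow_flexion", 0, c(-0.1, 2.6))
  )

  # the clavicle strut: a zero-DOF joint at the sternoclavicular joint that
  # keeps the clavicle aimed at the scapula's acromial facet, so clavicular
  # muscle attachments ride with the shoulder girdle
  ac_scap <- to_local("scapula", an$landmarks$AC)
  aim_ref <- an$landmarks$AC - an$sc_joint
  joints <- list(
    list(name = "ground_thorax", type = "weld", parent = "ground",
         child = "thorax", parent_offset = diag(4), coords = character(0),
         params = list()),
    list(name = "scapulothoracic", type = "ellipsoid", parent = "thorax",
         child = "scapula", parent_offset = st_offset,
         coords = c("scap_abduction", "scap_elevation", "scap_upward_rot",
                    "scap_winging"),
         params = list(radii = an$st_radii)),
    list(name = "sternoclavicular", type = "aim", parent = "thorax",
         child = "clavicle", parent_offset = T_clav, coords = character(0),
         params = list(target_body = "scapula", target_point = ac_scap,
                       aim_ref = aim_ref)),
    list(name = "glenohumeral", type = "ball", parent = "scapula",
         child = "humerus",
         parent_offset = transform_inverse(T_scap) %*% T_hum,
         coords = c("gh_plane", "gh_elev", "gh_rot"),
         params = list()),
    list(name = "elbow", type = "hinge", parent = "humerus",
         child = "forearm_hand",
         parent_offset = make_transform(diag(3), an$elbow - an$gh_center),
         coords = "elbow_flexion", params = list(axis = c(0, 0, 1)))
  )

  wraps <- list(
    thorax_wrap = wrap_surface("thorax_wrap", "ellipsoid", "thorax",
                               xform = make_transform(R_tilt %*% rot_z(-wrap_tilt),
                                                      an$st_center),
                               radii = an$st_radii * 0.96),
    gh_wrap = wrap_surface("gh_wrap", "sphere", "humerus",
                           xform = diag(4), radii = 0.024)
  )

  tab <- builtin_muscle_table()
  geo <- .fixture_muscle_geometry()
  stopifnot(identical(sort(tab$name), sort(names(geo))))
  muscles <- vector("list", nrow(tab))
  names(muscles) <- tab$name
  for (i in seq_len(nrow(tab))) {
    g <- geo[[tab$name[i]]]
    bnames <- sub("^thorax2$", "thorax", names(g$points))
    pts <- do.call(rbind, lapply(seq_along(g$points), function(k)
      to_local(names(g$points)[k], g$points[[k]])))
    path <- muscle_path(data.frame(body = bnames, x = pts[, 1], y = pts[, 2],
                                   z = pts[, 3], stringsAsFactors = FALSE),
                        wraps = g$wraps)
    muscles[[i]] <- list(
      params = muscle_parameters(tab$name[i], tab$group[i], tab$f_max[i],
                                 tab$l_opt[i], tab$l_ts[i], tab$pennation[i],
                                 tab$source_bundles[i]),
      path = path)
  }

  marker_body <- c(C7 = "thorax", T8 = "thorax", IJ = "thorax", PX = "thorax",
                   TS = "scapula", AI = "scapula", AA = "scapula", AC = "scapula",
                   EL = "humerus", EM = "humerus",
                   RS = "forearm_hand", US = "forearm_hand")
  markers <- lapply(names(marker_body), function(nm)
    model_marker(nm, marker_body[[nm]],
                 to_local(marker_body[[nm]], .fixture_anatomy()$landmarks[[nm]])))
  names(markers) <- names(marker_body)

  shoulder_model(
    name = "thoracoscapular_fixture",
    bodies = bodies, joints = joints, coordinates = coords,
    muscles = muscles, wraps = wraps, markers = markers,
    gravity = c(0, -9.81, 0),
    hand_mass = hand_mass,
    hand_point = list(body = "forearm_hand",
                      loc = to_local("forearm_hand", an$hand))
  )
}

#' Functional muscle grouping used by the work analysis
#'
#' Maps each actuator of a model to `"thoracoscapular"` (thorax/spine to
#' scapula: trapezius, serratus anterior, rhomboids, levator scapulae,
#' pectoralis minor), `"glenohumeral"` (crossing the glenohumeral joint:
#' deltoids, rotator cuff, teres major, plus latissimus dorsi, pectoralis
#' major, coracobrachialis, biceps and triceps which cross it anatomically)
#' or `"other"`.
#'
#' @param model a [shoulder_model()].
#' @return data.frame with columns `muscle`, `group`.
#' @export
muscle_groups <- function(model) {
  nm <- names(model$muscles)
  thoraco <- grepl("^(Trapezius|SerratusAnterior|Rhomboideus|LevatorScapulae|PectoralisMinor)",
                   nm)
  gh <- grepl("^(Deltoideus|Supraspinatus|Infraspinatus|TeresMinor|Subscapularis|TeresMajor|LatissimusDorsi|PectoralisMajor|Coracobrachialis|Biceps|TricepsLong)",
              nm)
  data.frame(muscle = nm,
             group = ifelse(thoraco, "thoracoscapular",
                            ifelse(gh, "glenohumeral", "other")),
             stringsAsFactors = FALSE)
}
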