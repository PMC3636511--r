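#' Anthropometrics for joint-centre estimation
#'
#' Offsets (mm) used to turn surface markers into virtual joint centres.
#' The exact offsets are subject-specific measurements; zeros make every
#' centre coincide with its source marker (the convention for idealised
#' synthetic subjects, whose markers are point joints).
#'
#' @param shoulder_offset_mm Inferior translation of the acromion along the
#'   trunk axis to the glenohumeral centre.
#' @param elbow_width_mm Elbow width; the centre sits half of it from the
#'   lateral epicondyle along the local flexion axis.
#' @param wrist_thickness_mm Wrist thickness; analogous half-offset.
#' @return A named list.
#' @export
anthropometrics <- function(shoulder_offset_mm = 40, elbow_width_mm = 60,
                            wrist_thickness_mm = 40) {
  list(
    shoulder_offset_mm = shoulder_offset_mm,
    elbow_width_mm = elbow_width_mm,
    wrist_thickness_mm = wrist_thickness_mm
  )
}

#' Estimate virtual joint centres from surface markers
#'
#' Shoulder centre: acromion translated inferiorly along the trunk
#' longitudinal axis (C7-sternum based) by `shoulder_offset_mm`. Elbow
#' centre: lateral epicondyle offset along the local flexion axis (normal of
#' the shoulder-elbow-wrist plane) by half the elbow width. Wrist centre:
#' wrist marker offset by half the wrist thickness along the local
#' elbow-wrist-hand normal. Finger joint centre: the first MCP marker
#' itself. Frames missing any input marker stay masked.
#'
#' @param rec A `bow_recording`.
#' @param anthro An [anthropometrics()] list. A missing entry is an error
#'   naming the subject and field.
#' @return A `bow_joint_centers` tibble: `frame`, `time`, `joint`
#'   (`shoulder`, `elbow`, `wrist`, `finger`), `x`, `y`, `z`, `present`;
#'   per-joint provenance attached as attribute `provenance`.
#' @export
estimate_joint_centers <- function(rec, anthro = anthropometrics()) {
  for (field in c("shoulder_offset_mm", "elbow_width_mm",
    "wrist_thickness_mm")) {
    if (is.null(anthro[[field]]) || is.na(anthro[[field]])) {
      abort(sprintf(
        "missing anthropometric entry '%s' for subject %s",
        field, attr(rec, "subject_id")
      ))
    }
  }
  fs <- rec_fs(rec)
  sternum <- marker_xyz(rec, "sternum")
  c7 <- marker_xyz(rec, "c7")
  acromion <- marker_xyz(rec, "acromion")
  elbow <- marker_xyz(rec, "elbow_lat")
  wrist <- marker_xyz(rec, "wrist")
  mcp <- marker_xyz(rec, "hand_mcp1")

  # a zero offset must not inherit missingness from the markers that only
  # serve to construct the offset axis
  trunk_up <- unit_rows(c7 - sternum)
  shoulder_c <- if (anthro$shoulder_offset_mm == 0) {
    acromion
  } else {
    acromion - anthro$shoulder_offset_mm * trunk_up
  }

  elbow_c <- if (anthro$elbow_width_mm == 0) {
    elbow
  } else {
    elbow + (anthro$elbow_width_mm / 2) *
      unit_rows(cross3(shoulder_c - elbow, wrist - elbow))
  }

  wrist_c <- if (anthro$wrist_thickness_mm == 0) {
    wrist
  } else {
    wrist + (anthro$wrist_thickness_mm / 2) *
      unit_rows(cross3(elbow_c - wrist, mcp - wrist))
  }

  finger_c <- mcp

  rows <- rec$marker == "sternum"
  frame <- rec$frame[rows]
  time <- rec$time[rows]
  build <- function(joint, p) {
    present <- !is.na(p[, 1]) & !is.na(p[, 2]) & !is.na(p[, 3])
    tibble::tibble(
      frame = frame, time = time, joint = joint,
      x = ifelse(present, p[, 1], NA_real_),
      y = ifelse(present, p[, 2], NA_real_),
      z = ifelse(present, p[, 3], NA_real_),
      present = present
    )
  }
  out <- dplyr::bind_rows(
    build("shoulder", shoulder_c),
    build("elbow", elbow_c),
    build("wrist", wrist_c),
    build("finger", finger_c)
  )
  out$joint <- factor(out$joint,
    levels = c("shoulder", "elbow", "wrist", "finger")
  )
  structure(out,
    fs = fs,
    provenance = c(
      shoulder = "acromion + trunk-axis offset",
      elbow = "lateral epicondyle + half elbow width along flexion axis",
      wrist = "wrist marker + half wrist thickness along local normal",
      finger = "first MCP marker (direct)"
    ),
    class = c("bow_joint_centers", class(out))
  )
}

# internal: positions of one joint centre as an n x 3 matrix
center_xyz <- function(jc, joint) {
  rows <- jc$joint == joint
  cbind(jc$x[rows], jc$y[rows], jc$z[rows])
}

#' Cello-centred coordinate frame
#'
#' Builds the instrument frame from the three cello markers: origin at the
#' scroll marker, string axis scroll -> tailpiece, lateral axis the
#' component of scroll -> body orthogonal to the string axis, normal axis
#' their right-handed completion. By default the frame is computed from the
#' trial-median cello marker positions (the cello is quasi-static and this
#' keeps cello-marker noise out of the bow kinematics).
#'
#' @param rec A `bow_recording`.
#' @return A list with `origin` and a 3x3 rotation matrix `axes` whose
#'   columns are the string, lateral and normal unit axes.
#' @export
cello_frame <- function(rec) {
  med <- function(m) {
    p <- marker_xyz(rec, m)
    apply(p, 2, median, na.rm = TRUE)
  }
  scroll <- med("cello_scroll")
  tail <- med("cello_tail")
  body <- med("cello_body")
  string <- tail - scroll
  sn <- sqrt(sum(string^2))
  if (sn < 1e-9) abort("cello scroll and tail markers coincide")
  string <- string / sn
  lat <- body - scroll
  lat <- lat - sum(lat * string) * string
  ln <- sqrt(sum(lat^2))
  if (ln < 1e-6) abort("cello markers are collinear; lateral axis undefined")
  lat <- lat / ln
  normal <- c(
    string[2] * lat[3] - string[3] * lat[2],
    string[3] * lat[1] - string[1] * lat[3],
    string[1] * lat[2] - string[2] * lat[1]
  )
  list(origin = scroll, axes = cbind(
    string = string, lateral = lat,
    normal = normal
  ))
}

#' Transform a recording to cello-centred coordinates
#'
#' Expresses every marker position in the [cello_frame()] of the trial. The
#' transform is rigid, so all inter-marker distances are preserved and any
#' global rigid motion of the captured scene cancels out.
#'
#' @param rec A `bow_recording`.
#' @return The transformed `bow_recording`.
#' @export
to_cello_frame <- function(rec) {
  cf <- cello_frame(rec)
  parts <- rec_split(rec)
  for (m in parts$markers) {
    p <- parts$pos[[m]]
    parts$pos[[m]] <- sweep(p, 2, cf$origin, "-") %*% cf$axes
  }
  rec_rebuild(rec, parts$pos, parts$present)
}

#' Compute joint angles of the bowing arm
#'
#' Angles in degrees, one time series per joint, from the trunk markers and
#' virtual joint centres: shoulder abduction (elevation of the
#' shoulder -> elbow vector away from the downward trunk axis), elbow
#' flexion (180 deg minus the angle at the elbow, so a straight arm reads
#' 0), wrist flexion (angle between forearm and hand directions), finger
#' flexion (angle between hand and proximal-phalanx directions). Larger
#' positive values mean more abducted / more flexed. Frames with a
#' degenerate (zero-length) segment are masked.
#'
#' @param rec A `bow_recording` (for the trunk and hand markers).
#' @param jc Matching [estimate_joint_centers()] output.
#' @return A `bow_joint_angles` tibble: `frame`, `time`, `joint`
#'   (`shoulder`, `elbow`, `wrist`, `finger`), `angle_deg`, `present`.
#' @export
compute_joint_angles <- function(rec, jc) {
  fs <- rec_fs(rec)
  sternum <- marker_xyz(rec, "sternum")
  c7 <- marker_xyz(rec, "c7")
  pip <- marker_xyz(rec, "hand_pip1")
  shoulder <- center_xyz(jc, "shoulder")
  elbow <- center_xyz(jc, "elbow")
  wrist <- center_xyz(jc, "wrist")
  hand <- center_xyz(jc, "finger")

  trunk_up <- unit_rows(c7 - sternum)
  ang <- joint_angles_from_points(shoulder, elbow, wrist, hand, pip, trunk_up)

  rows <- rec$marker == "sternum"
  frame <- rec$frame[rows]
  time <- rec$time[rows]
  out <- purrr::map_dfr(names(ang), function(j) {
    short <- sub("_(abduction|flexion)$", "", j)
    a <- ang[[j]]
    tibble::tibble(
      frame = frame, time = time, joint = short,
      angle_deg = a, present = !is.na(a)
    )
  })
  out$joint <- factor(out$joint,
    levels = c("shoulder", "elbow", "wrist", "finger")
  )
  structure(out, fs = fs, class = c("bow_joint_angles", class(out)))
}
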