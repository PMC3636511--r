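# small vector-geometry helpers shared by preprocessing and the generator

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n < 1e-12] <- NA_real_
  m / n
}

cross3 <- function(u, v) {
  cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
}

# angle between row vectors, degrees in [0, 180]
angle_rows_deg <- function(u, v) {
  un <- unit_rows(u)
  vn <- unit_rows(v)
  d <- rowSums(un * vn)
  d <- pmin(pmax(d, -1), 1)
  acos(d) * 180 / pi
}

rot_x <- function(a) {
  rbind(
    c(1, 0, 0),
    c(0, cos(a), -sin(a)),
    c(0, sin(a), cos(a))
  )
}

rot_z <- function(a) {
  rbind(
    c(cos(a), -sin(a), 0),
    c(sin(a), cos(a), 0),
    c(0, 0, 1)
  )
}

# joint angle set (degrees) from point trajectories; each argument is an
# n x 3 matrix. Conventions: larger positive = more abducted (shoulder,
# elevation of the upper arm away from the downward trunk axis) or more
# flexed (elbow, wrist, finger); a straight chain gives 0 flexion.
joint_angles_from_points <- function(shoulder, elbow, wrist, hand, finger2,
                                     trunk_up) {
  if (is.null(dim(trunk_up))) {
    trunk_up <- matrix(trunk_up,
      nrow = nrow(shoulder), ncol = 3,
      byrow = TRUE
    )
  }
  list(
    shoulder_abduction = angle_rows_deg(elbow - shoulder, -trunk_up),
    elbow_flexion = 180 - angle_rows_deg(shoulder - elbow, wrist - elbow),
    wrist_flexion = angle_rows_deg(wrist - elbow, hand - wrist),
    finger_flexion = angle_rows_deg(hand - wrist, finger2 - hand)
  )
}
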