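#' Marker and section layout of one instrumented tape
#'
#' Seven sections per tape, delimited by the two anchors and six interior
#' marker stations at equal spacing. Eleven markers: an outer-edge marker
#' at every station (6), inner-edge markers at the two stations nearest
#' each anchor (4), and one shared inner-edge marker at the exact tape
#' center, which belongs to the marker pairs of both central stations. The
#' back and front sections connect their two tape markers to the (known)
#' anchor coordinates; the middle section therefore has three markers and
#' every other section four (counting anchors separately).
#'
#' @param geom A [device_geometry()].
#' @return A list of class `section_layout` with `boundaries` (8 x
#'   coordinates including the anchors), `markers` (data.frame: `label`,
#'   `x_mm`, `edge`, `edge_offset_mm`), and `section_members` (list of 7
#'   character vectors of marker labels; `"@anchor_back"`/`"@anchor_front"`
#'   denote the anchor points).
#' @export
luna_layout <- function(geom) {
  stopifnot(inherits(geom, "tape_geometry"))
  L <- geom$span_l_mm
  half <- L / 2
  w <- geom$tape_width_mm / 2
  st <- -half + (1:6) * L / 7          # interior stations t1..t6
  markers <- data.frame(
    label = c(paste0("out", 1:6), "in1", "in2", "inC", "in5", "in6"),
    x_mm = c(st, st[1], st[2], 0, st[5], st[6]),
    edge = c(rep("outer", 6), rep("inner", 5)),
    edge_offset_mm = c(rep(w, 6), rep(-w, 5)),
    stringsAsFactors = FALSE
  )
  members <- list(
    c("@anchor_back", "out1", "in1"),
    c("out1", "in1", "out2", "in2"),
    c("out2", "in2", "out3", "inC"),
    c("out3", "inC", "out4"),
    c("out4", "inC", "out5", "in5"),
    c("out5", "in5", "out6", "in6"),
    c("out6", "in6", "@anchor_front")
  )
  structure(list(boundaries = c(-half, st, half), markers = markers,
                 section_members = members, geom = geom),
            class = "section_layout")
}

#' Optimal rigid alignment of two matched point sets (Kabsch)
#'
#' Returns the proper rotation (determinant +1) and translation minimizing
#' the root-mean-square deviation between matched 3D point sets, via the
#' SVD of the cross-covariance matrix with the standard sign correction.
#'
#' @param ref,obs Numeric matrices (n x 3), n >= 3, matched row-by-row.
#' @return A list with `rotation` (3 x 3, maps centered ref to centered
#'   obs), `translation` (length 3: `obs_centroid - rotation %*%
#'   ref_centroid`), and `rmsd` (mm).
#' @export
kabsch_transform <- function(ref, obs) {
  ref <- as.matrix(ref); obs <- as.matrix(obs)
  stopifnot(ncol(ref) == 3, ncol(obs) == 3, nrow(ref) == nrow(obs),
            nrow(ref) >= 3, all(is.finite(ref)), all(is.finite(obs)))
  cr <- colMeans(ref); co <- colMeans(obs)
  p <- sweep(ref, 2, cr); q <- sweep(obs, 2, co)
  sv <- svd(crossprod(p, q))             # H = P' Q
  if (sv$d[2] < max(sv$d[1], 1) * 1e-10) {
    stop("degenerate (collinear) point configuration")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- p %*% t(R)
  rmsd <- sqrt(mean(rowSums((q - fit)^2)))
  list(rotation = R, translation = as.numeric(co - R %*% cr), rmsd = rmsd)
}

#' Compose a rotation from Tait-Bryan XYZ-intrinsic angles
#'
#' `R = Rx(roll) %*% Ry(pitch) %*% Rz(yaw)`: intrinsic rotations about X,
#' then the rotated Y, then the twice-rotated Z.
#'
#' @param roll_deg,pitch_deg,yaw_deg Angles in degrees.
#' @return A 3 x 3 rotation matrix.
#' @export
taitbryan_matrix <- function(roll_deg, pitch_deg, yaw_deg) {
  cf <- cos(deg2rad(roll_deg)); sf <- sin(deg2rad(roll_deg))
  ct <- cos(deg2rad(pitch_deg)); st <- sin(deg2rad(pitch_deg))
  cp <- cos(deg2rad(yaw_deg)); sp <- sin(deg2rad(yaw_deg))
  rx <- matrix(c(1, 0, 0, 0, cf, sf, 0, -sf, cf), 3, 3)
  ry <- matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3, 3)
  rz <- matrix(c(cp, sp, 0, -sp, cp, 0, 0, 0, 1), 3, 3)
  rx %*% ry %*% rz
}

#' Tait-Bryan XYZ-intrinsic angles of a rotation
#'
#' Decomposes a proper rotation as `Rx(roll) Ry(pitch) Rz(yaw)`. The
#' decomposition round-trips through [taitbryan_matrix()] to machine
#' precision away from the gimbal singularity; proximity to it (|pitch|
#' near 90 degrees) is flagged via the `"gimbal"` attribute.
#'
#' @param R A 3 x 3 proper rotation matrix.
#' @return Named numeric vector `c(roll_deg, pitch_deg, yaw_deg)` with a
#'   logical attribute `"gimbal"`.
#' @export
taitbryan_xyz <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == 3))
  dimnames(R) <- NULL
  if (abs(det(R) - 1) > 1e-6 || max(abs(crossprod(R) - diag(3))) > 1e-6) {
    stop("R is not a proper rotation matrix")
  }
  s <- max(-1, min(1, R[1, 3]))
  gimbal <- abs(s) > 1 - 1e-8
  pitch <- asin(s)
  if (gimbal) {
    # yaw and roll are degenerate; attribute everything to roll
    roll <- atan2(R[2, 1], R[2, 2])
    yaw <- 0
  } else {
    yaw <- atan2(-R[1, 2], R[1, 1])
    roll <- atan2(-R[2, 3], R[3, 3])
  }
  out <- c(roll_deg = rad2deg(roll), pitch_deg = rad2deg(pitch),
           yaw_deg = rad2deg(yaw))
  attr(out, "gimbal") <- gimbal
  out
}

#' Per-section rigid transforms and angles from one marker frame
#'
#' Reconstructs each tape section's rotation relative to the rest pose by
#' Kabsch-aligning its marker set (the back and front sections additionally
#' use the fixed anchor coordinates from the geometry), then extracts
#' Tait-Bryan XYZ-intrinsic angles. Angles are reported in the device
#' frame; use [anchor_angles_from_sections()] to obtain model inputs with
#' the downward/leftward-positive sign normalization.
#'
#' A missing marker invalidates only the sections it belongs to (their
#' angles become `NA`); the remaining sections are still reconstructed.
#'
#' @param markers Data.frame for one frame: `label`, `x_mm`, `y_mm`,
#'   `z_mm`.
#' @param layout A [luna_layout()].
#' @param rest Optional rest-pose marker data.frame (same schema); default
#'   is the unloaded layout pose (z = 0, edges at rest width).
#' @return Data.frame with one row per section: `section`, `roll_deg`,
#'   `pitch_deg`, `yaw_deg`, `x_center_mm`, `y_center_mm`, `z_center_mm`,
#'   `rmsd_mm`.
#' @export
section_angles <- function(markers, layout, rest = NULL) {
  stopifnot(inherits(layout, "section_layout"))
  geom <- layout$geom
  if (is.null(rest)) {
    rest <- data.frame(label = layout$markers$label,
                       x_mm = layout$markers$x_mm,
                       y_mm = layout$markers$edge_offset_mm,
                       z_mm = 0, stringsAsFactors = FALSE)
  }
  anchors <- rbind("@anchor_back" = c(geom$anchor_x_mm[1], 0, 0),
                   "@anchor_front" = c(geom$anchor_x_mm[2], 0, 0))
  lookup <- function(df, lab) {
    if (startsWith(lab, "@")) return(anchors[lab, ])
    i <- match(lab, df$label)
    if (is.na(i)) return(NULL)
    as.numeric(df[i, c("x_mm", "y_mm", "z_mm")])
  }
  ns <- length(layout$section_members)
  out <- data.frame(section = seq_len(ns), roll_deg = NA_real_,
                    pitch_deg = NA_real_, yaw_deg = NA_real_,
                    x_center_mm = NA_real_, y_center_mm = NA_real_,
                    z_center_mm = NA_real_, rmsd_mm = NA_real_)
  for (sct in seq_len(ns)) {
    labs <- layout$section_members[[sct]]
    ref <- lapply(labs, lookup, df = rest)
    obs <- lapply(labs, lookup, df = markers)
    if (any(vapply(ref, is.null, logical(1))) ||
        any(vapply(obs, is.null, logical(1)))) next
    ref <- do.call(rbind, ref); obs <- do.call(rbind, obs)
    kt <- kabsch_transform(ref, obs)
    tb <- taitbryan_xyz(kt$rotation)
    out$roll_deg[sct] <- tb[["roll_deg"]]
    out$pitch_deg[sct] <- tb[["pitch_deg"]]
    out$yaw_deg[sct] <- tb[["yaw_deg"]]
    ctr <- colMeans(obs)
    out$x_center_mm[sct] <- ctr[1]
    out$y_center_mm[sct] <- ctr[2]
    out$z_center_mm[sct] <- ctr[3]
    out$rmsd_mm[sct] <- kt$rmsd
  }
  out
}

#' Model input angles from reconstructed section angles
#'
#' Picks the back (1) and front (last) section angles and applies the sign
#' normalization expected by the inverse model: the front pitch and yaw are
#' negated so that both ends read positive for downward, respectively +Y,
#' displacement.
#'
#' @param sections Data.frame from [section_angles()] (one frame).
#' @return One-row data.frame with the six normalized angle columns.
#' @export
anchor_angles_from_sections <- function(sections) {
  b <- sections[1, ]
  f <- sections[nrow(sections), ]
  data.frame(pitch_back_deg = b$pitch_deg, pitch_front_deg = -f$pitch_deg,
             yaw_back_deg = b$yaw_deg, yaw_front_deg = -f$yaw_deg,
             roll_back_deg = b$roll_deg, roll_front_deg = f$roll_deg)
}
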