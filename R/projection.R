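#' C-arm cone-beam geometry
#'
#' Idealized C-arm acquisition geometry, mirroring the DICOM positioner
#' attributes. World frame: origin at the isocenter, +x patient left,
#' +y patient anterior, +z patient head. At angulation (0, 0) the X-ray
#' source sits at (0, -SISOD, 0) and the detector plane at
#' y = SID - SISOD (anteroposterior view). The primary angle (LAO
#' positive / RAO negative) rotates the source-detector assembly about the
#' head-feet axis z, the secondary angle (CRAN positive / CAUD negative)
#' about the left-right axis x; the assembly rotation is
#' `R = R_x(secondary) %*% R_z(primary)`.
#'
#' @param primary_angle,secondary_angle C-arm angulation, degrees.
#' @param sid source-image distance, mm.
#' @param sisod source-to-isocenter distance, mm (0 < sisod < sid).
#' @param pixel_spacing detector pixel spacing, mm/px (scalar or per axis
#'   (u, v)).
#' @param detector_size detector size in pixels (u, v).
#' @param isocenter_px principal-point pixel coordinates (u, v), 1-based;
#'   defaults to the detector center.
#' @return An object of class `carm_geometry`.
#' @export
carm_geometry <- function(primary_angle = 0, secondary_angle = 0,
                          sid = 1200, sisod = 800, pixel_spacing = 0.3,
                          detector_size = c(256, 256), isocenter_px = NULL) {
  stopifnot(sid > 0, sisod > 0, sisod < sid, all(pixel_spacing > 0),
            all(detector_size >= 1))
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  detector_size <- rep_len(as.integer(detector_size), 2L)
  if (is.null(isocenter_px)) isocenter_px <- (detector_size + 1) / 2
  structure(list(primary_angle = primary_angle,
                 secondary_angle = secondary_angle, sid = sid, sisod = sisod,
                 pixel_spacing = pixel_spacing,
                 detector_size = detector_size,
                 isocenter_px = rep_len(as.numeric(isocenter_px), 2L)),
            class = "carm_geometry")
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# source position, detector axes and view direction in world coordinates
carm_frame <- function(g) {
  Rk <- rot_x(g$secondary_angle) %*% rot_z(g$primary_angle)
  list(src = as.numeric(Rk %*% c(0, -g$sisod, 0)),
       view = as.numeric(Rk %*% c(0, 1, 0)),     # central-ray direction
       u_axis = as.numeric(Rk %*% c(1, 0, 0)),
       v_axis = as.numeric(Rk %*% c(0, 0, -1)))  # image v down = patient head up
}

#' Build the 3x4 cone-beam projection matrix
#'
#' `P = K [R | t]` for the pinhole model of the C-arm: focal lengths
#' `SID / pixel_spacing`, principal point at `isocenter_px` (so the world
#' isocenter projects exactly onto it), camera rotation/translation from
#' the angulated source-detector assembly. The matrix is normalized so
#' that the first three entries of its third row (the unit ray direction)
#' have norm 1; it is defined up to scale.
#'
#' @param g a [carm_geometry()].
#' @return A 3 x 4 matrix of class `projection_matrix`.
#' @export
build_projection_matrix <- function(g) {
  fr <- carm_frame(g)
  R_cam <- rbind(fr$u_axis, fr$v_axis, fr$view)
  K <- matrix(c(g$sid / g$pixel_spacing[1], 0, 0,
                0, g$sid / g$pixel_spacing[2], 0,
                g$isocenter_px[1], g$isocenter_px[2], 1), 3, 3)
  P <- K %*% cbind(R_cam, -R_cam %*% fr$src)
  structure(P / sqrt(sum(P[3, 1:3]^2)), class = "projection_matrix")
}

#' Project world points to detector pixels
#'
#' Homogeneous multiply and dehomogenize: `(u, v, w) = P (x, y, z, 1)`,
#' pixel = (u/w, v/w).
#'
#' @param P a [build_projection_matrix()] result (or any 3 x 4 matrix).
#' @param p length-3 vector or n x 3 matrix of world points, mm.
#' @return n x 2 matrix of pixel coordinates (u, v).
#' @export
project_point <- function(P, p) {
  p <- as_points(p)
  h <- unclass(P) %*% rbind(t(p), 1)
  w <- h[3, ]
  if (any(abs(w) < 1e-12))
    stop("projection at infinity: point on the source plane")
  cbind(u = h[1, ] / w, v = h[2, ] / w)
}

#' Ray-cast a concentration volume into a projection image
#'
#' For each detector pixel a ray from the source through the pixel center
#' is sampled equidistantly through the volume bounding box; the trilinear
#' concentration samples are summed and scaled by the step length, a
#' numerical line integral of concentration (attenuation) along the ray.
#'
#' @param conc a [concentration_volume()].
#' @param g a [carm_geometry()].
#' @param step ray sampling step, mm; defaults to half the smallest voxel
#'   spacing.
#' @return Image matrix `[v, u]` of line integrals (mm * concentration).
#' @export
raycast_volume <- function(conc, g, step = NULL) {
  stopifnot(inherits(conc, "concentration_volume"),
            inherits(g, "carm_geometry"))
  if (is.null(step)) step <- min(conc$grid$spacing) / 2
  stopifnot(step > 0)
  fr <- carm_frame(g)
  det_center <- fr$src + g$sid * fr$view
  cu <- g$isocenter_px[1]; cv <- g$isocenter_px[2]
  det00 <- det_center + (1 - cu) * g$pixel_spacing[1] * fr$u_axis +
    (1 - cv) * g$pixel_spacing[2] * fr$v_axis
  img <- cpp_raycast(as.numeric(conc$values), conc$grid$shape,
                     conc$grid$spacing, conc$grid$origin, fr$src, det00,
                     g$pixel_spacing[1] * fr$u_axis,
                     g$pixel_spacing[2] * fr$v_axis,
                     g$detector_size[1], g$detector_size[2], step)
  if (all(img == 0) && any(conc$values != 0))
    warning("volume is outside the view frustum: all-zero image")
  img
}

#' Render a virtual DSA sequence
#'
#' Ray-casts every concentration snapshot with the same C-arm geometry.
#' Raw line integrals are returned (contrast bright); `invert = TRUE`
#' flips the sign for DSA-style display (contrast dark).
#'
#' @param concs a `transport_result` or list of [concentration_volume()]s
#'   sharing one grid.
#' @param g a [carm_geometry()].
#' @param frame_rate frames per second of the output; taken from the
#'   `transport_result` when available.
#' @param step ray sampling step, mm.
#' @param invert invert intensities for display.
#' @return An [image_sequence()] tagged `"virtual"`.
#' @export
render_sequence <- function(concs, g, frame_rate = NULL, step = NULL,
                            invert = FALSE) {
  if (inherits(concs, "transport_result")) {
    if (is.null(frame_rate)) frame_rate <- concs$frame_rate
    concs <- concs$snapshots
  }
  stopifnot(length(concs) >= 2)
  if (is.null(frame_rate)) stop("frame_rate is required for a snapshot list")
  g0 <- concs[[1]]$grid
  for (cc in concs)
    if (!all(cc$grid$shape == g0$shape) ||
        !all(abs(cc$grid$spacing - g0$spacing) < 1e-9))
      stop("sequence error: snapshots have inconsistent grids")
  frames <- vapply(concs, function(cc) raycast_volume(cc, g, step),
                   matrix(0, g$detector_size[2], g$detector_size[1]))
  if (invert) frames <- max(frames) - frames
  image_sequence(frames, frame_rate,
                 pixel_spacing = mean(g$pixel_spacing), source = "virtual")
}
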