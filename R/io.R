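#' Write / read a scalar volume as NIfTI
#'
#' Spacing is stored in the NIfTI pixdim; the origin is carried in the
#' accompanying JSON manifests the pipeline writes (NIfTI srow handling is
#' deliberately not relied on for these synthetic volumes).
#'
#' @param values numeric array (3D).
#' @param grid a [grid_spec()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, grid, path) {
  img <- RNifti::asNifti(array(as.numeric(values), dim = grid$shape))
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param origin world coordinates of the first voxel center, mm.
#' @return For `read_volume`: list with `values` and `grid`.
#' @export
read_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  list(values = vals,
       grid = grid_spec(dim(img), RNifti::pixdim(img)[1:3], origin))
}

#' Write an image sequence as a TIFF stack plus JSON manifest
#'
#' Frames are stored as 32-bit float TIFF pages scaled to `[0, 1]`; the
#' manifest records the intensity scale, frame rate and pixel spacing so
#' [read_sequence()] restores the original values.
#'
#' @param seq an [image_sequence()].
#' @param path output TIFF path; the manifest is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  mx <- max(abs(seq$frames), 1e-12)
  pages <- lapply(seq_len(dim(seq$frames)[3]),
                  function(i) pmin(pmax(seq$frames[, , i] / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(frame_rate = seq$frame_rate,
                            pixel_spacing = seq$pixel_spacing,
                            intensity_scale = mx, source = seq$source,
                            n_frames = dim(seq$frames)[3]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequence
#' @param frame_rate override for plain TIFF stacks without a manifest.
#' @return For `read_sequence`: an [image_sequence()].
#' @export
read_sequence <- function(path, frame_rate = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  man_path <- paste0(path, ".json")
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path,
                                                        simplifyVector = TRUE)
  if (is.null(frame_rate)) {
    if (is.null(man)) stop("frame rate unknown: no manifest and no override")
    frame_rate <- man$frame_rate
  }
  scale <- if (!is.null(man$intensity_scale)) man$intensity_scale else 1
  frames <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse any channel dim
    p * scale
  }, matrix(0, nrow(pages[[1]]), ncol(pages[[1]])))
  image_sequence(frames, frame_rate,
                 pixel_spacing = if (!is.null(man$pixel_spacing))
                   man$pixel_spacing else 1,
                 source = if (!is.null(man$source)) man$source else "real")
}

#' Export a TIC as CSV
#'
#' Two columns, `time_s` and `intensity`.
#'
#' @param tic a [tic_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tic_csv <- function(tic, path) {
  write.csv(data.frame(time_s = tic$times, intensity = tic$intensities),
            path, row.names = FALSE)
  invisible(path)
}

#' Dump per-frame particle positions as CSV
#'
#' One row per particle and frame: `t, x, y, z` (for streak/path
#' visualization). Requires `simulate_transport(..., keep_particles =
#' TRUE)`.
#'
#' @param result a `transport_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles_csv <- function(result, path) {
  if (is.null(result$particle_frames))
    stop("run simulate_transport with keep_particles = TRUE")
  rows <- do.call(rbind, lapply(seq_along(result$particle_frames),
    function(i) {
      p <- result$particle_frames[[i]]
      if (!nrow(p)) return(NULL)
      data.frame(t = result$times[i], x = p[, 1], y = p[, 2], z = p[, 3])
    }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write concentration snapshots as a NIfTI series plus manifest
#'
#' @param result a `transport_result`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The manifest path, invisibly.
#' @export
write_snapshots <- function(result, dir, prefix = "conc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(result$snapshots))
  for (i in seq_along(result$snapshots)) {
    files[i] <- file.path(dir, sprintf("%s_%04d.nii.gz", prefix, i))
    sn <- result$snapshots[[i]]
    write_volume(sn$values, sn$grid, files[i])
  }
  g <- result$snapshots[[1]]$grid
  man <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(list(files = basename(files), times_s = result$times,
                            frame_rate = result$frame_rate,
                            grid = list(shape = g$shape, spacing = g$spacing,
                                        origin = g$origin),
                            units = "particles/mm^3"),
                       man, auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Read a C-arm geometry from JSON
#'
#' Accepts either the package's field names or DICOM-style attribute names
#' (PositionerPrimaryAngle, PositionerSecondaryAngle,
#' DistanceSourceToDetector, DistanceSourceToPatient, ImagerPixelSpacing).
#'
#' @param path JSON file path.
#' @return A [carm_geometry()].
#' @export
read_carm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(j[[nm]])) return(j[[nm]])
    NULL
  }
  carm_geometry(
    primary_angle = pick("primary_angle", "PositionerPrimaryAngle") %||% 0,
    secondary_angle = pick("secondary_angle",
                           "PositionerSecondaryAngle") %||% 0,
    sid = pick("sid", "DistanceSourceToDetector") %||% 1200,
    sisod = pick("sisod", "DistanceSourceToPatient") %||% 800,
    pixel_spacing = pick("pixel_spacing", "ImagerPixelSpacing") %||% 0.3,
    detector_size = pick("detector_size") %||% c(256, 256),
    isocenter_px = pick("isocenter_px"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
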