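#' Write a voxel grid (or multichannel scene) as multipage TIFF
#'
#' Each z plane becomes one TIFF page; multichannel scenes are written as
#' one file per channel (`<prefix>_<channel>.tif`).  Intensities are
#' rescaled to [0, 1] 32-bit float pages; the scale factor and voxel size
#' are recorded in a JSON sidecar so stacks round-trip exactly.
#'
#' @param x a [voxel_grid()] or a named list of them.
#' @param path output file (single grid) or prefix (channel list).
#' @return invisibly, the file(s) written.
#' @export
write_stack_tiff <- function(x, path) {
  if (inherits(x, "voxel_grid")) {
    scale <- max(abs(x$data), 1e-12)
    pages <- lapply(seq_len(dim(x$data)[3]), function(z)
      t(x$data[, , z]) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta <- list(voxel_size_um = x$voxel_size, channel = x$channel,
                 intensity_scale = scale, dim = dim(x$data))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(path))
  }
  files <- vapply(names(x), function(ch) {
    f <- paste0(path, "_", ch, ".tif")
    write_stack_tiff(x[[ch]], f)
    f
  }, character(1))
  invisible(files)
}

#' Read a multipage TIFF written by [write_stack_tiff()]
#'
#' @param path the TIFF file; its `.json` sidecar must sit next to it.
#' @return a [voxel_grid()].
#' @export
read_stack_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dim)
  a <- array(0, d)
  for (z in seq_along(pages)) a[, , z] <- t(pages[[z]]) * meta$intensity_scale
  voxel_grid(a, as.numeric(meta$voxel_size_um), meta$channel)
}

#' Write the ground-truth point table of a scene as CSV
#'
#' Columns: cell_id, object_type, x_um, y_um, z_um, partner_id, angle_rad.
#'
#' @param truth result of [sample_ground_truth()] (or the `truth` element of
#'   [render_stack()]).
#' @param path output CSV path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  df <- truth$points
  out <- data.frame(cell_id = df$cell_id, object_type = df$type,
                    x_um = df$x_um, y_um = df$y_um, z_um = df$z_um,
                    partner_id = df$partner_id, angle_rad = df$angle_rad)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a scene specification as JSON
#' @param spec a [scene_spec()].
#' @param path output JSON path.
#' @export
write_scene_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
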