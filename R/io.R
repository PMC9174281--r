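## coordinate-table and TIFF input/output.

#' Column mapping for external coordinate tables
#'
#' Describes how a delimited coordinate table maps onto the package's
#' observation columns, including the z convention: published tables often
#' store z in isotropic units (1 unit = dx), from which the slice index is
#' recovered by dividing by \code{zDivisor} (dz/dx, 2.5 at 0.8/0.8/2.0 um
#' spacing); tables storing the raw slice index are converted to isotropic
#' units on read.
#'
#' @param embryo_id,frame,time,x,y,z source column names.
#' @param volume optional source column with the nucleus voxel volume.
#' @param zUnits "isotropic" (default) or "slice".
#' @param zDivisor dz/dx ratio used for the slice conversion.
#' @param sep field separator of the file.
#' @return a list used by \code{\link{readCoordinates}}.
#' @export
coordinateMapping <- function(embryo_id = "embryo_id", frame = "frame",
                              time = "time_h", x = "x", y = "y",
                              z = "z_isotropic", volume = "volume_voxels",
                              zUnits = c("isotropic", "slice"),
                              zDivisor = 2.5, sep = "\t") {
  list(embryo_id = embryo_id, frame = frame, time = time, x = x, y = y,
       z = z, volume = volume, zUnits = match.arg(zUnits),
       zDivisor = zDivisor, sep = sep)
}

#' Read a nucleus coordinate table
#'
#' Reads a delimited table through a \code{\link{coordinateMapping}},
#' validates it (missing columns, non-numeric coordinates and duplicate
#' (embryo, frame, position) rows raise errors naming the offending rows)
#' and returns observations in the package convention (z isotropic).
#'
#' @param path file path.
#' @param mapping a \code{\link{coordinateMapping}}.
#' @return nucleus-observation data.frame.
#' @export
readCoordinates <- function(path, mapping = coordinateMapping()) {
  raw <- utils::read.table(path, header = TRUE, sep = mapping$sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("embryo_id", "frame", "time", "x", "y", "z")
  for (field in need) {
    if (!mapping[[field]] %in% names(raw))
      stop("mapped column '", mapping[[field]], "' (", field,
           ") not found in ", path)
  }
  num <- function(field) {
    v <- raw[[mapping[[field]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad))
      stop("non-numeric ", field, " in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path)
    out
  }
  obs <- data.frame(embryo_id = as.character(raw[[mapping$embryo_id]]),
                    frame = as.integer(num("frame")),
                    time_h = num("time"), x = num("x"), y = num("y"),
                    z = num("z"))
  obs$volume <- if (!is.null(mapping$volume) && mapping$volume %in% names(raw))
    suppressWarnings(as.numeric(raw[[mapping$volume]])) else NA_real_
  if (mapping$zUnits == "slice") obs$z <- obs$z * mapping$zDivisor
  dup <- duplicated(obs[, c("embryo_id", "frame", "x", "y", "z")])
  if (any(dup))
    stop("duplicate (embryo, frame, position) in row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "), " of ", path)
  message(nrow(obs), " observation(s), ",
          length(unique(obs$embryo_id)), " embryo(s) read from ", path)
  asObservations(obs)
}

#' Write a nucleus coordinate table
#'
#' Tab-separated, with the package's standard columns (embryo_id, frame,
#' time_h, x, y, z_isotropic, volume_voxels); the default
#' \code{\link{coordinateMapping}} reads it back unchanged.
#'
#' @param observations nucleus-observation data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCoordinates <- function(observations, path) {
  obs <- asObservations(observations)
  names(obs) <- c("embryo_id", "frame", "time_h", "x", "y", "z_isotropic",
                  "volume_voxels")
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Slice index from an isotropic z coordinate
#'
#' @param z z in isotropic units (1 unit = dx).
#' @param zDivisor dz/dx ratio (2.5 at the default spacing).
#' @return the (fractional, 0-based) slice index.
#' @export
sliceIndex <- function(z, zDivisor = 2.5) z / zDivisor

#' Write a VoxelGrid as a multi-page TIFF
#'
#' One page per z slice, z ascending. Intensities are scaled to a maximum of
#' 1 on write (the TIFF stores relative intensity); 32-bit samples.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVolumeTIFF <- function(grid, path) {
  v <- intensities(grid)
  mx <- max(v)
  if (mx > 1) v <- v / mx
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page TIFF z stack as a VoxelGrid
#'
#' @param path TIFF path (pages = z slices, ascending).
#' @param spacing voxel pitch (dx, dy, dz), micrometres.
#' @param time frame time, hours.
#' @param frameIndex frame number.
#' @return a \linkS4class{VoxelGrid}.
#' @export
readVolumeTIFF <- function(path, spacing = c(0.8, 0.8, 2.0), time = 0,
                           frameIndex = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  v <- vapply(pages, t, matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  voxelGrid(array(v, dim = c(dim(pages[[1]])[2], dim(pages[[1]])[1],
                             length(pages))),
            spacing = spacing, time = time, frameIndex = frameIndex)
}
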