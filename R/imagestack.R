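#' Calibrated multi-channel image stack
#'
#' Container for a multi-frame, multi-channel (optionally multi-slice)
#' intensity image with physical calibration. Pixel data are stored as a
#' numeric array with axes `T, C, Y, X` or `T, C, Z, Y, X`.
#'
#' Coordinate convention (used throughout the package): pixels are 0-based,
#' `(row, col) = (y, x)`, pixel centers sit at integer coordinates, and
#' physical positions are `pixel * pixel_size` micrometres. Angles are
#' reported in degrees in \[0, 360), with the math convention applied to
#' `(x, -y)` so that visually counterclockwise is positive.
#'
#' @param pixels numeric array with dimensions `(T, C, Y, X)` or
#'   `(T, C, Z, Y, X)`.
#' @param pixel_size um/pixel, > 0.
#' @param frame_interval min/frame; required (> 0) when `T > 1`.
#' @param z_step um between z slices (z-stacks only).
#' @param channel_names character vector of length C.
#' @return object of class `ImageStack`.
#' @export
ImageStack <- function(pixels, pixel_size, frame_interval = NA_real_,
                       z_step = NA_real_, channel_names = NULL) {
  nd <- length(dim(pixels))
  assert_that(nd %in% c(4L, 5L),
              "pixels must be a (T,C,Y,X) or (T,C,Z,Y,X) array")
  assert_pos(pixel_size, "pixel_size")
  nT <- dim(pixels)[1]; nC <- dim(pixels)[2]
  if (nT > 1L)
    assert_that(is.finite(frame_interval) && frame_interval > 0,
                "calibration error: frame_interval must be > 0 for a time series")
  channel_names <- channel_names %||% paste0("ch", seq_len(nC))
  assert_that(length(channel_names) == nC,
              "channel_names length must equal the number of channels")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval, z_step = z_step,
                 channel_names = as.character(channel_names)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  axes <- if (length(d) == 5L) "T,C,Z,Y,X" else "T,C,Y,X"
  cat("ImageStack [", paste(d, collapse = " x "), "] (", axes, ")\n", sep = "")
  cat("  pixel size:", x$pixel_size, "um/px; frame interval:",
      x$frame_interval, "min\n")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one 2-D frame from a stack
#'
#' Returns the `(Y, X)` matrix of frame `t`, channel `ch` (name or index).
#' For 5-D stacks the maximal z-projection is returned.
#'
#' @param stack an [ImageStack].
#' @param t frame index (1-based).
#' @param ch channel name or index.
#' @return numeric matrix `(Y, X)`.
#' @export
get_frame <- function(stack, t = 1L, ch = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(ch)) {
    ch <- match(ch, stack$channel_names)
    assert_that(!is.na(ch), "unknown channel name")
  }
  d <- dim(stack$pixels)
  if (length(d) == 4L) {
    matrix(stack$pixels[t, ch, , ], d[3], d[4])
  } else {
    apply(array(stack$pixels[t, ch, , , ], d[3:5]), c(2, 3), max)
  }
}

#' @noRd
sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as multi-page TIFF plus calibration sidecar
#'
#' Pages are written frame-major, channel-minor (`T, C` order), 16-bit.
#' Calibration and axis metadata are written to a JSON sidecar
#' `<path>.json` so that [read_stack()] restores the stack losslessly.
#' Pixel values must be integer counts in \[0, 65535\].
#'
#' @param stack an [ImageStack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$pixels)
  assert_that(length(d) == 4L, "write_stack currently writes T,C,Y,X stacks")
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    pages[[k]] <- pmin(pmax(round(matrix(stack$pixels[t, ch, , ], d[3], d[4])),
                            0), 65535) / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(axes = "TCYX", n_frames = d[1], n_channels = d[2],
               shape = c(d[3], d[4]), pixel_size_um = stack$pixel_size,
               frame_interval_min = stack$frame_interval,
               z_step_um = stack$z_step, channel_names = stack$channel_names)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Axes are normalised to `T, C, Y, X`. Calibration comes from the JSON
#' sidecar written by [write_stack()] unless overridden; a single-page TIFF
#' with no sidecar becomes a `T = 1, C = 1` stack, and a multi-page TIFF
#' with no sidecar is interpreted as a pure time series (`C = 1`). Missing
#' pixel size with no override is a calibration error.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval,z_step calibration overrides.
#' @param channel_names optional channel name override.
#' @return an [ImageStack].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       z_step = NULL, channel_names = NULL) {
  assert_that(file.exists(path), sprintf("format error: no such file '%s'", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("format error: unreadable TIFF: ", conditionMessage(e),
                           call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # drop extra samples per pixel
    pg
  })
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  nP <- length(pages)
  nT <- meta$n_frames %||% nP
  nC <- meta$n_channels %||% 1L
  assert_that(nT * nC == nP, "format error: page count inconsistent with metadata")
  sh <- dim(pages[[1]])
  pixels <- array(0, dim = c(nT, nC, sh[1], sh[2]))
  k <- 1L
  for (t in seq_len(nT)) for (ch in seq_len(nC)) {
    pixels[t, ch, , ] <- pages[[k]]
    k <- k + 1L
  }
  px <- pixel_size %||% meta$pixel_size_um
  assert_that(!is.null(px),
              "calibration error: pixel_size not in metadata and no override given")
  fi <- frame_interval %||% meta$frame_interval_min %||% NA_real_
  ImageStack(pixels, pixel_size = px, frame_interval = fi,
             z_step = z_step %||% meta$z_step_um %||% NA_real_,
             channel_names = channel_names %||% meta$channel_names)
}

#' Write analysis result tables to a directory
#'
#' Writes each element of a named list of data.frames as
#' `<out_dir>/<name>.csv` (header always written, even for empty tables) and
#' a `summary.json` manifest with row counts. Objects of class
#' `angular_distribution` are expanded into an angle table and a rose
#' histogram table (`bin_start_deg`, `fraction`); `rao_test` objects are
#' written into the JSON summary.
#'
#' @param results named list of data.frames / `angular_distribution` /
#'   `rao_test` objects.
#' @param out_dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  assert_that(is.list(results) && !is.null(names(results)) &&
                all(nzchar(names(results))), "results must be a named list")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(ok && file.access(out_dir, 2) == 0,
              sprintf("I/O error: cannot write to '%s'", out_dir))
  files <- character(0)
  summary <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "angular_distribution")) {
      f1 <- file.path(out_dir, paste0(nm, "_angles.csv"))
      utils::write.csv(data.frame(angle_deg = x$angles), f1, row.names = FALSE)
      f2 <- file.path(out_dir, paste0(nm, "_rose.csv"))
      utils::write.csv(data.frame(bin_start_deg = as.numeric(names(x$bin_fractions)),
                                  fraction = as.numeric(x$bin_fractions)),
                       f2, row.names = FALSE)
      files <- c(files, f1, f2)
      summary[[nm]] <- list(n_endosomes = x$n_endosomes, n_cells = x$n_cells,
                            front_quadrant_fraction = x$front_quadrant_fraction)
    } else if (inherits(x, "rao_test")) {
      summary[[nm]] <- unclass(x)
    } else {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(x), f, row.names = FALSE)
      files <- c(files, f)
      summary[[nm]] <- list(rows = nrow(as.data.frame(x)))
    }
  }
  jf <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, jf))
}
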