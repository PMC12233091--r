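# ImageJ .roi files are big-endian binary records: a 64-byte header
# ("Iout", version, roi type, bounding box, vertex count) followed by the
# vertex coordinates as 16-bit integers relative to the bounding box.
# Polygon ROIs have type 0, polylines type 5. ImageJ coordinates are
# 0-based with x = column and y = row; conversion from the internal
# 1-based (row, col) convention happens here and only here.

IJ_TYPE_POLYGON <- 0L
IJ_TYPE_POLYLINE <- 5L

#' Export an ROI as an ImageJ .roi file
#'
#' Polygon ROIs are written as ImageJ polygon ROIs, segmented lines as
#' polyline ROIs. Coordinates are rounded to integers and written 0-based
#' in ImageJ's x/y (column/row) convention, so the files load directly in
#' ImageJ. Integer-coordinate ROIs round-trip exactly through
#' [import_path()].
#'
#' @param roi a [roi_polygon()] or [segmented_line()].
#' @param path output file path.
#' @export
export_roi <- function(roi, path) {
  if (inherits(roi, "roi_polygon")) {
    pts <- roi$vertices
    type <- IJ_TYPE_POLYGON
  } else if (inherits(roi, "segmented_line")) {
    pts <- roi$points
    type <- IJ_TYPE_POLYLINE
  } else {
    stopf("export_roi needs a roi_polygon or segmented_line")
  }
  x <- round(pts[, 2]) - 1L  # ImageJ x = 0-based column
  y <- round(pts[, 1]) - 1L  # ImageJ y = 0-based row
  left <- min(x); top <- min(y)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stopf("cannot write '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeChar("Iout", con, 4, eos = NULL)
  writeBin(228L, con, size = 2, endian = "big")               # version
  writeBin(as.integer(type), con, size = 1)                   # roi type
  writeBin(0L, con, size = 1)
  writeBin(as.integer(c(top, left, max(y) + 1L, max(x) + 1L)), con,
           size = 2, endian = "big")                          # top,left,bottom,right
  writeBin(as.integer(length(x)), con, size = 2, endian = "big")
  writeBin(numeric(4), con, size = 4, endian = "big")         # x1,y1,x2,y2
  writeBin(integer(15), con, size = 2, endian = "big")        # remaining header
  writeBin(as.integer(x - left), con, size = 2, endian = "big")
  writeBin(as.integer(y - top), con, size = 2, endian = "big")
  invisible(path)
}

read_ij_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout") {
    stopf("'%s' is not an ImageJ .roi file", path)
  }
  int16 <- function(off) {  # big-endian signed short at 0-based offset
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  }
  type <- as.integer(raw[7])
  top <- int16(8); left <- int16(10)
  n <- int16(16)
  if (n < 1) stopf("'%s' contains no coordinates", path)
  xs <- readBin(raw[65:(64 + 2 * n)], "integer", size = 2, n = n, endian = "big")
  ys <- readBin(raw[(65 + 2 * n):(64 + 4 * n)], "integer", size = 2, n = n, endian = "big")
  pts <- cbind(row = ys + top + 1, col = xs + left + 1)  # back to 1-based (row, col)
  list(type = type, points = pts)
}

#' Import a medial-axis / polyline path
#'
#' Accepts either a polyline-type ImageJ `.roi` file (e.g. written by
#' [export_roi()] or by ImageJ itself) or a plain-text CSV array dump with
#' two columns `(row, col)`. Polygon-type `.roi` files are rejected: a path
#' is an open polyline, not a closed region.
#'
#' @param path input file.
#' @return a [segmented_line()] with the control points in internal pixel
#'   coordinates.
#' @export
import_path <- function(path) {
  if (!file.exists(path)) stopf("cannot read path file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "roi") {
    r <- read_ij_roi(path)
    if (r$type != IJ_TYPE_POLYLINE) {
      stopf("'%s' is not a polyline .roi (type %d); paths must be polylines",
            path, r$type)
    }
    return(segmented_line(r$points))
  }
  m <- as.matrix(read.csv(path, header = FALSE))
  if (ncol(m) != 2) stopf("array dump '%s' must have two columns (row, col)", path)
  storage.mode(m) <- "double"
  segmented_line(m)
}

#' Import a polygon ROI from an ImageJ .roi file
#'
#' @param path input `.roi` file of polygon type.
#' @return a [roi_polygon()].
#' @export
import_polygon <- function(path) {
  r <- read_ij_roi(path)
  if (r$type != IJ_TYPE_POLYGON) {
    stopf("'%s' is not a polygon .roi (type %d)", path, r$type)
  }
  roi_polygon(r$points)
}
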