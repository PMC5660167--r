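# Planar geometry helpers shared by the simulator and the morphometry module.
# Polygons are n x 2 matrices with columns (x, y) = (column, row) in pixel
# units; pixel (i, j) has centre (x = j, y = i) and extends 0.5 px each way.

# linear indices of a digital disc of radius r centred at (r0, c0),
# clipped to an nr x nc image
disc_pixels <- function(nr, nc, r0, c0, r) {
  k <- ceiling(r)
  rows <- (r0 - k):(r0 + k)
  cols <- (c0 - k):(c0 + k)
  rows <- rows[rows >= 1 & rows <= nr]
  cols <- cols[cols >= 1 & cols <= nc]
  if (!length(rows) || !length(cols)) return(integer(0))
  dr2 <- (rows - r0)^2
  dc2 <- (cols - c0)^2
  keep <- outer(dr2, dc2, "+") <= r^2
  idx <- outer(rows, (cols - 1L) * nr, "+")
  as.integer(idx[keep])
}

# convex hull polygon over the *corners* of a pixel set, so that caliper
# widths include the physical pixel extent (a w x h pixel block has widths
# exactly w and h)
pixels_to_polygon <- function(rows, cols) {
  stopifnot(length(rows) == length(cols), length(rows) >= 1L)
  h1 <- grDevices::chull(cols, rows)
  cx <- cols[h1]; cy <- rows[h1]
  corn_x <- c(cx - 0.5, cx + 0.5, cx - 0.5, cx + 0.5)
  corn_y <- c(cy - 0.5, cy - 0.5, cy + 0.5, cy + 0.5)
  h2 <- grDevices::chull(corn_x, corn_y)
  cbind(x = corn_x[h2], y = corn_y[h2])
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

#' Minimum Feret (lesser) diameter of a polygon
#'
#' The minimum over all orientations of the caliper (projection) width of the
#' polygon's convex hull. The minimum width of a convex polygon is attained
#' perpendicular to one of its edges, so scanning the hull-edge normals is
#' exact (rotating-calipers candidate set).
#'
#' This is the standard "lesser fibre diameter" of muscle morphometry: for an
#' obliquely sectioned cylindrical fibre the caliper minimum recovers the true
#' cross-sectional diameter.
#'
#' @param polygon an n x 2 matrix of (x, y) vertices, n >= 3, not all
#'   collinear. Vertex order is irrelevant (the convex hull is taken).
#' @return The lesser diameter, in the units of the vertex coordinates.
#' @examples
#' sq <- cbind(c(0, 4, 4, 0), c(0, 0, 9, 9))
#' min_feret(sq)  # 4
#' @export
min_feret <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (!is.numeric(polygon) || ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("`polygon` must be a numeric matrix with >= 3 rows and 2 columns")
  h <- grDevices::chull(polygon[, 1], polygon[, 2])
  if (length(h) < 3L)
    stop("degenerate polygon: fewer than 3 hull vertices (collinear input)")
  hx <- polygon[h, 1]; hy <- polygon[h, 2]
  n <- length(h)
  j <- c(seq_len(n)[-1L], 1L)
  ex <- hx[j] - hx; ey <- hy[j] - hy
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  if (!any(keep)) stop("degenerate polygon: zero-length hull")
  # unit normals of hull edges
  nx <- -ey[keep] / len[keep]; ny <- ex[keep] / len[keep]
  proj <- outer(nx, hx) + outer(ny, hy)          # edges x vertices
  widths <- apply(proj, 1L, max) - apply(proj, 1L, min)
  min(widths)
}

# maximum caliper width (greatest Feret diameter): max pairwise hull distance
max_feret <- function(polygon) {
  polygon <- as.matrix(polygon)
  h <- grDevices::chull(polygon[, 1], polygon[, 2])
  hx <- polygon[h, 1]; hy <- polygon[h, 2]
  d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  sqrt(max(d2))
}
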