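# Shape descriptors from label masks: area, centroid, eccentricity,
# solidity, maximal Feret diameter.  Conventions follow the common
# region-properties toolchain: 8-connected regions, moments of pixel
# centers, convex hull over pixel centers.

# Pixel-center coordinates (um) of a label's pixels; mask rows index y.
.label_pixels <- function(mask, label) {
  stopifnot(inherits(mask, "mask_image"))
  idx <- which(mask$labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("label ", label, " not present in mask", call. = FALSE)
  }
  res <- mask$resolution
  origin <- if (is.null(mask$origin)) c(0, 0) else mask$origin
  data.frame(x = origin[1] + (idx[, "col"] - 0.5) * res,
             y = origin[2] + (idx[, "row"] - 0.5) * res)
}

#' Region area and centroid
#'
#' Area is the pixel count scaled by the squared resolution; the centroid
#' (center of gravity, the point the neighborhood analysis measures
#' distances between) is the mean of the pixel-center coordinates.
#'
#' @param mask a `mask_image` (see [rasterize_shapes()]).
#' @param label positive integer label.
#' @return list with `area_um2` and `centroid` (`c(x, y)` um).
#' @export
compute_area_centroid <- function(mask, label) {
  p <- .label_pixels(mask, label)
  list(area_um2 = nrow(p) * mask$resolution^2,
       centroid = c(mean(p$x), mean(p$y)))
}

#' Region eccentricity
#'
#' Eccentricity of the ellipse with the same normalized second central
#' moments as the region: `e = sqrt(1 - lambda_minor / lambda_major)` with
#' the lambdas the eigenvalues of the pixel-center covariance.  0 for a
#' circle (and by convention for a single pixel), 1 for a line.
#'
#' @inheritParams compute_area_centroid
#' @return eccentricity in \[0, 1\].
#' @export
compute_eccentricity <- function(mask, label) {
  p <- .label_pixels(mask, label)
  n <- nrow(p)
  if (n < 2L) return(0)
  mu20 <- mean((p$x - mean(p$x))^2)
  mu02 <- mean((p$y - mean(p$y))^2)
  mu11 <- mean((p$x - mean(p$x)) * (p$y - mean(p$y)))
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l_max <- (mu20 + mu02 + disc) / 2
  l_min <- (mu20 + mu02 - disc) / 2
  if (l_max <= 0) return(0)
  sqrt(max(0, 1 - l_min / l_max))
}

# Pixel count of the filled convex hull of a point set (pixel centers on a
# regular grid).  Convexity makes each row slice a single interval, so a
# scanline over the grid rows suffices.  Degenerate (collinear) hulls fill
# exactly the region's own pixels.
.hull_pixel_count <- function(p, resolution) {
  n <- nrow(p)
  if (n <= 2L) return(n)
  h <- grDevices::chull(p$x, p$y)
  if (length(h) < 3L) return(n)  # collinear region
  hx <- p$x[h]; hy <- p$y[h]
  rows <- sort(unique(p$y))
  # extend the row range over the hull's y-span
  all_rows <- seq(min(rows), max(rows), by = resolution)
  eps <- resolution * 1e-6
  m <- length(hx)
  nxt <- c(2:m, 1)
  x0 <- min(p$x)  # a grid column reference; columns are x0 + k * resolution
  count <- 0
  for (y0 in all_rows) {
    lo <- Inf; hi <- -Inf
    for (e in seq_len(m)) {
      y1 <- hy[e]; y2 <- hy[nxt[e]]
      x1 <- hx[e]; x2 <- hx[nxt[e]]
      if (abs(y1 - y0) <= eps) { lo <- min(lo, x1); hi <- max(hi, x1) }
      if ((y1 - y0) * (y2 - y0) < 0) {
        xc <- x1 + (y0 - y1) / (y2 - y1) * (x2 - x1)
        lo <- min(lo, xc); hi <- max(hi, xc)
      }
    }
    if (is.finite(lo) && hi >= lo) {
      # grid columns whose centers fall inside [lo, hi] on this row
      k_lo <- ceiling((lo - eps - x0) / resolution)
      k_hi <- floor((hi + eps - x0) / resolution)
      count <- count + max(0, k_hi - k_lo + 1)
    }
  }
  count
}

#' Region solidity
#'
#' Fraction of the pixels of the filled convex hull that belong to the
#' region.  1 for convex shapes; low solidity marks a frayed outline.
#'
#' @inheritParams compute_area_centroid
#' @return solidity in (0, 1\].
#' @export
compute_solidity <- function(mask, label) {
  p <- .label_pixels(mask, label)
  hull_n <- .hull_pixel_count(p, mask$resolution)
  min(1, nrow(p) / hull_n)
}

#' Maximal Feret diameter
#'
#' Largest distance between two parallel tangents over all orientations,
#' equal to the maximum pairwise distance between vertices of the convex
#' hull of the region's pixel centers.  A single pixel reports one pixel
#' width.
#'
#' @inheritParams compute_area_centroid
#' @return diameter in um.
#' @export
compute_feret_max <- function(mask, label) {
  p <- .label_pixels(mask, label)
  if (nrow(p) == 1L) return(mask$resolution)
  h <- unique(grDevices::chull(p$x, p$y))
  hx <- p$x[h]; hy <- p$y[h]
  if (length(h) == 1L) return(mask$resolution)
  d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  sqrt(max(d2))
}

#' Extract cell records from a label mask
#'
#' Runs all four descriptors per label and returns an [image_dataset()]
#' with unassigned profile classes, ready for classification.
#'
#' @param mask a `mask_image`.
#' @param image_id,diagnosis,resolution image metadata (the resolution
#'   defaults to the mask's own).
#' @return an `image_dataset`; empty mask gives an empty dataset.
#' @export
extract_features <- function(mask, image_id = "mask", diagnosis = "LA",
                             resolution = mask$resolution) {
  stopifnot(inherits(mask, "mask_image"))
  labels <- sort(setdiff(unique(as.vector(mask$labels)), 0L))
  rows <- lapply(labels, function(lb) {
    ac <- compute_area_centroid(mask, lb)
    data.frame(cell_id = lb,
               x_um = ac$centroid[1], y_um = ac$centroid[2],
               area_um2 = ac$area_um2,
               eccentricity = compute_eccentricity(mask, lb),
               solidity = compute_solidity(mask, lb),
               feret_um = compute_feret_max(mask, lb),
               pc = NA_integer_)
  })
  cells <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(cell_id = integer(0), x_um = numeric(0), y_um = numeric(0),
               area_um2 = numeric(0), eccentricity = numeric(0),
               solidity = numeric(0), feret_um = numeric(0),
               pc = integer(0))
  }
  image_dataset(cells, image_id, diagnosis, resolution = resolution)
}
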