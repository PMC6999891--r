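#' @keywords internal
"_PACKAGE"

# Column schema of the interchange cell table.  `pc` is optional on ingest:
# segmentation output carries no class; classification populates it.
.cell_columns <- c("cell_id", "x_um", "y_um", "area_um2",
                   "eccentricity", "solidity", "feret_um")

.diagnoses <- c("NScHL", "MCcHL", "LA")

#' Validate a data frame of cell records
#'
#' Checks the invariants of a cell table: positive unique ids, finite
#' coordinates, positive area, eccentricity in \[0, 1\], solidity in (0, 1\],
#' and a maximal Feret diameter at least the diameter of the disk of equal
#' area (up to a raster tolerance).  All violations are reported together
#' with their row numbers.
#'
#' @param cells data frame with columns
#'   `cell_id, x_um, y_um, area_um2, eccentricity, solidity, feret_um`
#'   and optionally `pc`.
#' @param feret_slack_um additive tolerance in um on the
#'   Feret >= equal-area-disk-diameter invariant, absorbing rasterization
#'   error on small digitized regions (default 1, about four pixels at the
#'   native resolution).
#' @return the validated data frame (invisibly unchanged), with an integer
#'   `pc` column added (all `NA`) when absent.
#' @export
validate_cells <- function(cells, feret_slack_um = 1) {
  stopifnot(is.data.frame(cells))
  missing_cols <- setdiff(.cell_columns, names(cells))
  if (length(missing_cols) > 0L) {
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"pc" %in% names(cells)) cells$pc <- NA_integer_
  n <- nrow(cells)
  if (n == 0L) return(invisible(cells))

  num_cols <- c(.cell_columns, "pc")
  bad <- character(0)
  for (col in .cell_columns) {
    v <- cells[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    rows <- which(!is.finite(v))
    if (length(rows) > 0L) {
      bad <- c(bad, sprintf("row %d: non-finite %s", rows, col))
    }
  }
  if (length(bad) == 0L) {
    chk <- function(rows, what) {
      if (length(rows) > 0L) sprintf("row %d: %s", rows, what) else character(0)
    }
    bad <- c(bad,
      chk(which(cells$cell_id <= 0 | cells$cell_id != floor(cells$cell_id)),
          "cell_id must be a positive integer"),
      chk(which(duplicated(cells$cell_id)), "duplicate cell_id"),
      chk(which(cells$area_um2 <= 0), "area_um2 must be > 0"),
      chk(which(cells$eccentricity < 0 | cells$eccentricity > 1),
          "eccentricity outside [0, 1]"),
      chk(which(cells$solidity <= 0 | cells$solidity > 1),
          "solidity outside (0, 1]"),
      chk(which(cells$feret_um <= 0), "feret_um must be > 0"),
      chk(which(cells$feret_um <
                equivalent_disk_diameter(cells$area_um2) - feret_slack_um),
          "feret_um below equal-area disk diameter"))
    pc <- cells$pc
    bad <- c(bad,
      chk(which(!is.na(pc) & (pc < 0 | pc > 7 | pc != floor(pc))),
          "pc outside 0..7"))
  }
  if (length(bad) > 0L) {
    stop("invalid cell table (", length(bad), " violation(s)):\n  ",
         paste(utils::head(bad, 20L), collapse = "\n  "), call. = FALSE)
  }
  cells$cell_id <- as.integer(cells$cell_id)
  cells$pc <- as.integer(cells$pc)
  invisible(cells)
}

#' Diameter of the disk with a given area
#'
#' @param area_um2 area(s) in square micrometers.
#' @return diameter(s) in micrometers, `2 * sqrt(area / pi)`.
#' @examples
#' equivalent_disk_diameter(109)   # ~11.8 um, the minimum-object diameter
#' @export
equivalent_disk_diameter <- function(area_um2) 2 * sqrt(area_um2 / pi)

#' Convert pixel lengths and areas to micrometers
#'
#' Geometry inside the package is resolution independent (micrometers);
#' conversion from pixel units happens once at ingest.
#'
#' @param n_px length in pixels.
#' @param resolution micrometers per pixel (default 0.25).
#' @return length in micrometers.
#' @export
px_to_um <- function(n_px, resolution = 0.25) n_px * resolution

#' @rdname px_to_um
#' @param n_px2 area in square pixels.
#' @export
px2_to_um2 <- function(n_px2, resolution = 0.25) n_px2 * resolution^2

#' Construct an image dataset
#'
#' Bundles the validated cell table of one whole slide image with its
#' metadata.  The observation window defaults to the bounding box of the
#' cell centroids (the tissue extent is not part of the interchange format).
#'
#' @param cells cell data frame (see [validate_cells()]).
#' @param image_id image identifier (coerced to character).
#' @param diagnosis one of `"NScHL"`, `"MCcHL"`, `"LA"`.
#' @param resolution micrometers per pixel of the source image (default 0.25).
#' @param window numeric `c(xmin, xmax, ymin, ymax)` in micrometers, or
#'   `NULL` to use the data extent.
#' @return an object of class `image_dataset`.
#' @export
image_dataset <- function(cells, image_id, diagnosis,
                          resolution = 0.25, window = NULL) {
  diagnosis <- match.arg(diagnosis, .diagnoses)
  cells <- validate_cells(cells)
  if (is.null(window)) {
    if (nrow(cells) > 0L) {
      window <- c(min(cells$x_um), max(cells$x_um),
                  min(cells$y_um), max(cells$y_um))
    } else {
      window <- c(0, 0, 0, 0)
    }
  }
  stopifnot(is.numeric(window), length(window) == 4L,
            window[1] <= window[2], window[3] <= window[4])
  if (nrow(cells) > 0L) {
    inside <- cells$x_um >= window[1] & cells$x_um <= window[2] &
              cells$y_um >= window[3] & cells$y_um <= window[4]
    if (!all(inside)) {
      stop("cell centroid(s) outside the observation window: rows ",
           paste(utils::head(which(!inside), 10L), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(image_id = as.character(image_id),
                 diagnosis = diagnosis,
                 resolution = resolution,
                 window = as.numeric(window),
                 cells = cells),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat("<image_dataset> id =", x$image_id, " diagnosis =", x$diagnosis, "\n")
  cat("  cells:", nrow(x$cells),
      " classified:", sum(!is.na(x$cells$pc)), "\n")
  cat(sprintf("  window: [%.1f, %.1f] x [%.1f, %.1f] um, %.2f um/px\n",
              x$window[1], x$window[2], x$window[3], x$window[4],
              x$resolution))
  invisible(x)
}

#' Read a cell table CSV into an image dataset
#'
#' The interchange format is a CSV with header
#' `cell_id,x_um,y_um,area_um2,eccentricity,solidity,feret_um[,pc]`.
#' Malformed rows never enter the pipeline: any invariant violation aborts
#' with the offending row numbers.
#'
#' @param path CSV file path.
#' @inheritParams image_dataset
#' @return an `image_dataset`.
#' @export
read_cell_table <- function(path, image_id, diagnosis,
                            resolution = 0.25, window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  image_dataset(cells, image_id = image_id, diagnosis = diagnosis,
                resolution = resolution, window = window)
}

#' Write an image dataset's cell table to CSV
#'
#' @param dataset an `image_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "image_dataset"))
  utils::write.csv(dataset$cells, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read and write cohort manifests
#'
#' A cohort manifest is a CSV `image_id,diagnosis,path` listing the cell
#' tables of a study; diagnosis labels must be `NScHL`, `MCcHL`, or `LA`.
#'
#' @param path manifest CSV path.
#' @return data frame with columns `image_id`, `diagnosis`, `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "diagnosis", "path")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!m$diagnosis %in% .diagnoses)
  if (length(bad) > 0L) {
    stop("manifest rows with unknown diagnosis: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m$image_id <- as.character(m$image_id)
  m[need]
}

#' @rdname read_manifest
#' @param manifest data frame with columns `image_id`, `diagnosis`, `path`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("image_id", "diagnosis", "path") %in% names(manifest)))
  utils::write.csv(manifest[c("image_id", "diagnosis", "path")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an 8 x 8 profile-class matrix
#'
#' Matrices inside the package are indexed `[PC + 1, NPC + 1]` (rows: the
#' focal cell's profile class; columns: the neighbor profile class).  On
#' disk the published orientation is used: CSV rows are NPC0..NPC7 and
#' columns PC0..PC7, with a leading `NPC` label column.  `read_matrix()`
#' inverts the layout, so `read_matrix(write_matrix(M)) == M`.
#'
#' @param m an 8 x 8 matrix (numeric or character).
#' @param path output CSV path.
#' @return `path` invisibly (writer); the matrix indexed `[PC+1, NPC+1]`
#'   (reader).
#' @export
write_matrix <- function(m, path) {
  if (!(is.matrix(m) && all(dim(m) == c(8L, 8L)))) {
    stop("matrix must be 8 x 8 (classes 0..7)", call. = FALSE)
  }
  disk <- t(m)  # rows NPC, columns PC
  df <- data.frame(NPC = paste0("NPC", 0:7), disk, check.names = FALSE)
  names(df) <- c("NPC", paste0("PC", 0:7))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df), c("NPC", paste0("PC", 0:7))) || nrow(df) != 8L) {
    stop("not an 8 x 8 profile-class matrix CSV: ", path, call. = FALSE)
  }
  disk <- as.matrix(df[, -1, drop = FALSE])
  m <- t(disk)  # back to [PC + 1, NPC + 1]
  dimnames(m) <- list(paste0("PC", 0:7), paste0("NPC", 0:7))
  m
}

#' Morphological classification thresholds
#'
#' The eight profile classes are cut by three thresholds: small/large on
#' area, round/elongated on eccentricity, and solid/frayed on solidity.
#' The published analysis defined its thresholds empirically with
#' pathologists; the exact values were not reprinted, so the defaults here
#' are documented stand-ins: the small/large boundary is the area of a
#' 20 um disk (tumor cells range from roughly 20 to 60 um in diameter).
#' Every threshold is configuration-exposed and echoed to output metadata.
#'
#' @param min_area minimum object area in um^2; objects of this size *or
#'   smaller* are discarded (default 109, an 11.8 um disk).
#' @param area_large small/large boundary in um^2 (default `100 * pi`
#'   = 314.16, a 20 um disk); large means `area >= area_large`.
#' @param ecc_elongated round/elongated boundary (default 0.75);
#'   elongated means `eccentricity >= ecc_elongated`.
#' @param solidity_frayed solid/frayed boundary (default 0.90); frayed
#'   means `solidity < solidity_frayed`.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(min_area = 109, area_large = 100 * pi,
                             ecc_elongated = 0.75, solidity_frayed = 0.90) {
  stopifnot(min_area >= 0, area_large > min_area,
            ecc_elongated > 0, ecc_elongated < 1,
            solidity_frayed > 0, solidity_frayed <= 1)
  structure(list(min_area = min_area, area_large = area_large,
                 ecc_elongated = ecc_elongated,
                 solidity_frayed = solidity_frayed),
            class = "threshold_config")
}

#' Analysis configuration
#'
#' Houses the tunable parameters of the whole pipeline with the study's
#' defaults: 175 um neighbor cutoff (700 px at 0.25 um/px), significance
#' level 1%, diameter bins of 2.5 um anchored at 0, the activated-lymphocyte
#' reference bin \[12.5, 15) um, and the 50%-of-maximum rule for network
#' edges.
#'
#' @param max_neighbor_distance neighbor search cutoff in um (default 175).
#' @param alpha two-sided significance level for the binomial prediction
#'   intervals, in (0, 1) (default 0.01).
#' @param diameter_bin_width diameter histogram bin width in um (default 2.5).
#' @param reference_bin `c(lo, hi)` um, the bin assumed to contain only
#'   background (activated-lymphocyte) cells (default `c(12.5, 15)`).
#' @param network_edge_fraction fraction of the maximal score a cohort
#'   entry must *exceed* to be drawn as a network edge, in (0, 1\]
#'   (default 0.5).
#' @param seed integer seed for the synthetic generator.
#' @param thresholds a [threshold_config()].
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(max_neighbor_distance = 175,
                            alpha = 0.01,
                            diameter_bin_width = 2.5,
                            reference_bin = c(12.5, 15),
                            network_edge_fraction = 0.5,
                            seed = 1L,
                            thresholds = threshold_config()) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(diameter_bin_width > 0)) stop("bin width must be > 0", call. = FALSE)
  if (!(max_neighbor_distance > 0)) {
    stop("max_neighbor_distance must be > 0", call. = FALSE)
  }
  if (!(network_edge_fraction > 0 && network_edge_fraction <= 1)) {
    stop("network_edge_fraction must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(length(reference_bin) == 2L, reference_bin[1] < reference_bin[2])
  if (!inherits(thresholds, "threshold_config")) {
    thresholds <- do.call(threshold_config, as.list(thresholds))
  }
  structure(list(max_neighbor_distance = max_neighbor_distance,
                 alpha = alpha,
                 diameter_bin_width = diameter_bin_width,
                 reference_bin = as.numeric(reference_bin),
                 network_edge_fraction = network_edge_fraction,
                 seed = as.integer(seed),
                 thresholds = thresholds),
            class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' Absent keys fall back to the defaults of [analysis_config()]; a nested
#' `thresholds:` block feeds [threshold_config()].  `path = NULL` (or an
#' empty file) returns the full default configuration.
#'
#' @param path YAML file, or `NULL` for defaults.
#' @return an `analysis_config`.
#' @export
load_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

# Append a stage line to a plain-text run log (count bookkeeping only).
log_stage <- function(log_path, stage, ...) {
  if (is.null(log_path)) return(invisible(NULL))
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(..., collapse = ""))
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  invisible(NULL)
}
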