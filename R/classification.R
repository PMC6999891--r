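# Profile classification: small-object filter and the eight-class bit code
# over (size, elongation, frayedness).

#' Remove small objects
#'
#' Objects of `min_area` *or less* are discarded (strictly greater areas
#' are retained), mirroring the segmentation pipeline's minimum object
#' size of 109 um^2 (an 11.8 um disk).
#'
#' @param dataset an `image_dataset` or a cell data frame.
#' @param min_area area threshold in um^2 (default 109).
#' @return same type as the input, with small objects removed.
#' @export
filter_small_objects <- function(dataset, min_area = 109) {
  if (inherits(dataset, "image_dataset")) {
    dataset$cells <- dataset$cells[dataset$cells$area_um2 > min_area, ,
                                   drop = FALSE]
    rownames(dataset$cells) <- NULL
    return(dataset)
  }
  out <- dataset[dataset$area_um2 > min_area, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign profile classes from shape descriptors
#'
#' The eight profile classes form a 3-bit code:
#' `pc = large + 2 * elongated + 4 * frayed`, with
#' `large = area >= area_large`, `elongated = eccentricity >=
#' ecc_elongated`, and `frayed = solidity < solidity_frayed`.
#' This reproduces the published naming exactly: 0 small round, 1 large
#' round, 2 small elongated, 3 large elongated, 4 small frayed, 5 large
#' frayed, 6 small elongated frayed, 7 large elongated frayed.
#'
#' @param dataset an `image_dataset` or cell data frame.
#' @param thresholds a [threshold_config()].
#' @return same type as input with the `pc` column populated.
#' @export
classify_cells <- function(dataset, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  cells <- if (inherits(dataset, "image_dataset")) dataset$cells else dataset
  pc <- as.integer(cells$area_um2 >= thresholds$area_large) +
        2L * as.integer(cells$eccentricity >= thresholds$ecc_elongated) +
        4L * as.integer(cells$solidity < thresholds$solidity_frayed)
  cells$pc <- pc
  if (inherits(dataset, "image_dataset")) {
    dataset$cells <- cells
    return(dataset)
  }
  cells
}

#' @rdname classify_cells
#' @param area_um2,eccentricity,solidity descriptors of a single cell.
#' @return `classify_cell()`: a single integer class in 0..7.
#' @export
classify_cell <- function(area_um2, eccentricity, solidity,
                          thresholds = threshold_config()) {
  as.integer(area_um2 >= thresholds$area_large) +
    2L * as.integer(eccentricity >= thresholds$ecc_elongated) +
    4L * as.integer(solidity < thresholds$solidity_frayed)
}

#' Relative profile-class frequencies
#'
#' `f(i) = count(i) / total` over all classified cells of the image;
#' these frequencies are the null-model neighbor probabilities of the
#' significance test.  The small/large aggregates split classes
#' \{0, 2, 4, 6\} (small) against \{1, 3, 5, 7\} (large).
#'
#' @param dataset an `image_dataset` or cell data frame with `pc` set.
#' @return numeric vector of length 8 (names `"0"`..`"7"`) summing to 1,
#'   with attributes `small`, `large`, and `n`.
#' @export
class_frequencies <- function(dataset) {
  cells <- if (inherits(dataset, "image_dataset")) dataset$cells else dataset
  pc <- cells$pc
  if (length(pc) == 0L) stop("empty dataset", call. = FALSE)
  if (anyNA(pc)) stop("dataset contains unclassified cells", call. = FALSE)
  counts <- tabulate(pc + 1L, nbins = 8L)
  f <- counts / sum(counts)
  names(f) <- as.character(0:7)
  attr(f, "small") <- sum(f[c(1, 3, 5, 7)])
  attr(f, "large") <- sum(f[c(2, 4, 6, 8)])
  attr(f, "n") <- sum(counts)
  f
}
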