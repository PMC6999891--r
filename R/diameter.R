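# Diameter distributions and background subtraction.  "Diameter" is the
# maximal Feret diameter throughout.  The identifying assumption of the
# background correction: the reference bin (default [12.5, 15) um)
# contains only activated-lymphocyte background, no tumor cells, so the
# ratio of the disease to the background histogram in that bin estimates
# the background admixture c, and 1 - c the tumor-cell proportion.

#' Diameter histogram of an image or cohort
#'
#' Relative frequencies of maximal Feret diameters in uniform half-open
#' bins `[lo, hi)` anchored at 0.
#'
#' @param x an `image_dataset`, a cell data frame, or a numeric vector of
#'   diameters (um).
#' @param bin_width bin width in um (default 2.5).
#' @param n_bins number of bins, or `NULL` to cover the data.
#' @return object of class `diameter_histogram`: list with `breaks`
#'   (length `n_bins + 1`), `freq` (sums to 1), `mids`, `n`, `bin_width`.
#' @export
diameter_histogram <- function(x, bin_width = 2.5, n_bins = NULL) {
  d <- if (inherits(x, "image_dataset")) x$cells$feret_um
       else if (is.data.frame(x)) x$feret_um
       else as.numeric(x)
  if (length(d) == 0L) stop("empty dataset", call. = FALSE)
  stopifnot(bin_width > 0, all(d >= 0))
  if (is.null(n_bins)) n_bins <- floor(max(d) / bin_width) + 1L
  idx <- floor(d / bin_width) + 1L  # half-open [lo, hi)
  if (any(idx > n_bins)) stop("n_bins too small for the data", call. = FALSE)
  counts <- tabulate(idx, nbins = n_bins)
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  structure(list(breaks = breaks,
                 freq = counts / length(d),
                 mids = breaks[-1] - bin_width / 2,
                 n = length(d), bin_width = bin_width),
            class = "diameter_histogram")
}

# pad two histograms with zero bins to a common length
.align_hists <- function(a, b) {
  if (a$bin_width != b$bin_width) {
    stop("histograms have different bin widths", call. = FALSE)
  }
  nb <- max(length(a$freq), length(b$freq))
  pad <- function(h) {
    extra <- nb - length(h$freq)
    if (extra > 0L) {
      h$freq <- c(h$freq, rep(0, extra))
      h$breaks <- seq(0, nb * h$bin_width, by = h$bin_width)
      h$mids <- h$breaks[-1] - h$bin_width / 2
    }
    h
  }
  list(a = pad(a), b = pad(b))
}

#' Background subtraction of the diameter distribution
#'
#' Scales the background (lymphadenitis) histogram to match the disease
#' histogram in the reference bin — assumed to contain background cells
#' only — and subtracts: `c = disease(ref) / background(ref)`,
#' `corrected(b) = max(0, disease(b) - c * background(b))`, renormalized.
#' The estimated tumor-cell (HRS) proportion is `1 - c`, clamped to
#' \[0, 1\].
#'
#' @param disease a [diameter_histogram()] of a disease cohort.
#' @param background a [diameter_histogram()] of the background cohort
#'   (LA).
#' @param reference_bin `c(lo, hi)` um; must coincide with one histogram
#'   bin (default `c(12.5, 15)`).
#' @return object of class `corrected_distribution`: list with `freq`
#'   (renormalized, clipped at 0), `mids`, `breaks`, scaling factor `c`,
#'   `proportion` (= 1 - c), `clipped_mass` (negative mass removed), and
#'   `bin_width`.
#' @export
background_correction <- function(disease, background,
                                  reference_bin = c(12.5, 15)) {
  stopifnot(inherits(disease, "diameter_histogram"),
            inherits(background, "diameter_histogram"))
  al <- .align_hists(disease, background)
  disease <- al$a; background <- al$b
  bw <- disease$bin_width
  ref_idx <- which(abs(disease$breaks[-length(disease$breaks)] -
                       reference_bin[1]) < 1e-9)
  if (length(ref_idx) != 1L ||
      abs(disease$breaks[ref_idx + 1L] - reference_bin[2]) > 1e-9) {
    stop("reference bin [", reference_bin[1], ", ", reference_bin[2],
         ") does not coincide with a histogram bin", call. = FALSE)
  }
  if (background$freq[ref_idx] <= 0) {
    stop("background frequency in the reference bin is zero",
         call. = FALSE)
  }
  c_hat <- disease$freq[ref_idx] / background$freq[ref_idx]
  raw <- disease$freq - c_hat * background$freq
  clipped_mass <- -sum(raw[raw < 0])
  corrected <- pmax(0, raw)
  total <- sum(corrected)
  freq <- if (total > 0) corrected / total else corrected
  structure(list(freq = freq, mids = disease$mids,
                 breaks = disease$breaks,
                 c = c_hat,
                 proportion = min(1, max(0, 1 - c_hat)),
                 clipped_mass = clipped_mass,
                 all_zero = total <= 0,
                 bin_width = bw),
            class = "corrected_distribution")
}

#' Moments of a corrected diameter distribution
#'
#' Mean and standard deviation over bin centers weighted by the corrected
#' frequencies, plus the tail fraction of bins whose center exceeds a
#' diameter threshold.
#'
#' @param corrected a [corrected_distribution()].
#' @param tail_threshold diameter in um for the tail fraction (default
#'   50).
#' @return named numeric `c(mean, sd, tail_fraction)` (um, um, unitless);
#'   error when the corrected distribution is all zero.
#' @export
corrected_moments <- function(corrected, tail_threshold = 50) {
  stopifnot(inherits(corrected, "corrected_distribution"))
  if (isTRUE(corrected$all_zero)) {
    stop("corrected distribution is all zero; moments undefined",
         call. = FALSE)
  }
  w <- corrected$freq
  m <- corrected$mids
  mu <- sum(w * m)
  sd <- sqrt(max(0, sum(w * m^2) - mu^2))
  c(mean = mu, sd = sd,
    tail_fraction = sum(w[m > tail_threshold]))
}

#' Write a diameter histogram or corrected distribution to CSV
#'
#' @param h a `diameter_histogram` or `corrected_distribution`.
#' @param path CSV path.
#' @export
write_histogram <- function(h, path) {
  df <- data.frame(bin_lo = h$breaks[-length(h$breaks)],
                   bin_hi = h$breaks[-1],
                   freq = h$freq)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bar plot of a diameter distribution
#'
#' @param height a `diameter_histogram` or `corrected_distribution`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_diameters <- function(height, ...) {
  graphics::barplot(height$freq, names.arg = height$mids,
                    xlab = "diameter [um]", ylab = "relative fraction",
                    ...)
  invisible(NULL)
}
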