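# Statistical core: exact binomial prediction intervals for the number of
# (PC = i, NPC = j) nearest-neighbor pairs, and per-image significance
# matrices of sh / sl / ns calls.
#
# Null model: if the nearest neighbor is chosen at random, the count k of
# class-i cells whose neighbor has class j is Binomial(n_i, f(j)), where
# f(j) is the relative frequency of class j among all classified cells of
# the image.  A two-sided exact prediction interval [k_low, k_up] at level
# alpha brackets the counts compatible with random choice:
#   k_low = max{ k : P(X <= k) <= alpha/2 }   (-1 when no such k)
#   k_up  = min{ k : P(X >= k) <= alpha/2 }   (n+1 when no such k)
# Counts strictly outside the interval are called sh (above) or sl
# (below); the endpoints themselves are ns.

#' Exact binomial cumulative probability
#'
#' `P(X <= k)` for `X ~ Binomial(n, p)`, evaluated exactly via the
#' regularized incomplete beta function (numerically stable up to
#' n = 1e6; no normal approximation).
#'
#' @param k count, `0 <= k <= n` (vectorized).
#' @param n number of trials.
#' @param p success probability in \[0, 1\].
#' @return cumulative probability.
#' @export
binom_cdf <- function(k, n, p) {
  if (any(n < 0) || any(k < 0) || any(k > n)) {
    stop("require 0 <= k <= n", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) stop("require 0 <= p <= 1", call. = FALSE)
  stats::pbinom(k, n, p)
}

#' @rdname binom_cdf
#' @return `binom_tail_upper()`: the upper tail `P(X >= k)`.
#' @export
binom_tail_upper <- function(k, n, p) {
  if (any(n < 0) || any(k < 0) || any(k > n)) {
    stop("require 0 <= k <= n", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) stop("require 0 <= p <= 1", call. = FALSE)
  ifelse(k == 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Exact binomial prediction interval
#'
#' Computes `[k_low, k_up]` by exact tail evaluation (see the definitions
#' above).  When no count satisfies the lower condition, `k_low = -1`;
#' when none satisfies the upper condition, `k_up = n + 1` — in either
#' case that side can never produce a significant call.
#'
#' @param n number of trials (class-i cells with a neighbor).
#' @param p null success probability (relative frequency of class j).
#' @param alpha two-sided level in (0, 1).
#' @return object of class `prediction_interval`: list with `k_low`,
#'   `k_up`, `n`, `p`, `alpha`.
#' @export
prediction_interval <- function(n, p, alpha = 0.01) {
  stopifnot(length(n) == 1L, length(p) == 1L, length(alpha) == 1L)
  if (!(alpha > 0 && alpha < 1)) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!(p >= 0 && p <= 1)) stop("require 0 <= p <= 1", call. = FALSE)
  if (!(n >= 0 && n == floor(n))) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  half <- alpha / 2
  # lower endpoint: largest k with CDF(k) <= alpha/2
  cand <- stats::qbinom(half, n, p)  # smallest k with CDF(k) >= alpha/2
  k_low <- if (n == 0L) -1 else {
    k <- cand
    while (k <= n && stats::pbinom(k, n, p) <= half) k <- k + 1
    k <- k - 1
    while (k >= 0 && stats::pbinom(k, n, p) > half) k <- k - 1
    k  # -1 when even CDF(0) > alpha/2
  }
  # upper endpoint: smallest k with P(X >= k) <= alpha/2
  cand <- stats::qbinom(1 - half, n, p)
  k_up <- if (n == 0L) 1 else {
    k <- max(0, cand)
    while (k >= 0 && binom_tail_upper(k, n, p) <= half) k <- k - 1
    k <- k + 1
    while (k <= n && binom_tail_upper(k, n, p) > half) k <- k + 1
    k  # n + 1 when even P(X >= n) > alpha/2
  }
  structure(list(k_low = as.numeric(k_low), k_up = as.numeric(k_up),
                 n = n, p = p, alpha = alpha),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("<prediction_interval> [%g, %g]  n = %d, p = %.4g, alpha = %g\n",
              x$k_low, x$k_up, x$n, x$p, x$alpha))
  invisible(x)
}

#' Significance call for an observed pair count
#'
#' `"sh"` (significantly high) strictly above `k_up`, `"sl"` strictly
#' below `k_low`, `"ns"` otherwise; the interval endpoints are `ns`.
#'
#' @param k observed pair count.
#' @param interval a [prediction_interval()].
#' @return one of `"sh"`, `"sl"`, `"ns"`.
#' @export
significance_call <- function(k, interval) {
  stopifnot(inherits(interval, "prediction_interval"),
            k >= 0, k <= interval$n)
  if (k > interval$k_up) "sh" else if (k < interval$k_low) "sl" else "ns"
}

#' Per-image significance matrix
#'
#' For every class combination `(i, j)`: `n` is the number of class-i
#' cells with a neighbor within the cutoff, `k` the number of those whose
#' neighbor has class j, and `p = f(j)` the relative frequency of class j
#' over *all* classified cells of the image (isolated cells included).
#' No multiple-testing correction is applied across the 64 combinations
#' by default; `adjust = "BH"` optionally applies Benjamini-Hochberg to
#' the per-combination two-sided p-values.
#'
#' @param dataset classified `image_dataset`.
#' @param table matching `nbr_table` (built by [nearest_neighbors()]).
#' @param alpha two-sided level (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return object of class `significance_matrix`: list with `image_id`,
#'   8 x 8 matrices `k`, `k_low`, `k_up`, `calls` (rows PC, columns NPC),
#'   the per-class trial counts `n`, frequencies `p`, and `alpha`.
#' @export
significance_matrix <- function(dataset, table, alpha = 0.01,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(dataset, "image_dataset"),
            inherits(table, "nbr_table"))
  f <- class_frequencies(dataset)
  n_i <- tabulate(table$pc + 1L, nbins = 8L)
  k <- matrix(0, 8L, 8L, dimnames = list(paste0("PC", 0:7),
                                         paste0("NPC", 0:7)))
  if (nrow(table) > 0L) {
    tab <- table(factor(table$pc, levels = 0:7),
                 factor(table$npc, levels = 0:7))
    k[] <- as.numeric(tab)
  }
  k_low <- k_up <- matrix(NA_real_, 8L, 8L, dimnames = dimnames(k))
  calls <- matrix("ns", 8L, 8L, dimnames = dimnames(k))
  pval <- matrix(1, 8L, 8L)
  for (i in 1:8) {
    if (n_i[i] == 0L) next  # empty row: all ns
    for (j in 1:8) {
      pint <- prediction_interval(n_i[i], f[j], alpha)
      k_low[i, j] <- pint$k_low
      k_up[i, j] <- pint$k_up
      calls[i, j] <- significance_call(k[i, j], pint)
      if (adjust == "BH") {
        lo <- binom_cdf(k[i, j], n_i[i], f[j])
        hi <- binom_tail_upper(k[i, j], n_i[i], f[j])
        pval[i, j] <- min(1, 2 * min(lo, hi))
      }
    }
  }
  if (adjust == "BH") {
    padj <- matrix(stats::p.adjust(pval, method = "BH"), 8L, 8L)
    calls[padj > alpha] <- "ns"
  }
  structure(list(image_id = dataset$image_id,
                 diagnosis = dataset$diagnosis,
                 k = k, k_low = k_low, k_up = k_up, calls = calls,
                 n = stats::setNames(n_i, paste0("PC", 0:7)),
                 p = f, alpha = alpha, adjust = adjust),
            class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat("<significance_matrix> image", x$image_id, "(", x$diagnosis, ")",
      "alpha =", x$alpha, "\n")
  disp <- x$calls
  disp[disp == "ns"] <- "."
  print(disp, quote = FALSE)
  invisible(x)
}

#' Conditional neighbor-class probabilities
#'
#' Row i gives `P(NPC = j | PC = i) = k_ij / sum_j k_ij`; each defined row
#' sums to 1.  Rows with no pairs are `NA` (flagged, not silently 0).
#'
#' @param table an `nbr_table`.
#' @return 8 x 8 numeric matrix (rows PC, columns NPC).
#' @export
conditional_probabilities <- function(table) {
  if (nrow(table) == 0L) stop("empty neighborhood table", call. = FALSE)
  tab <- table(factor(table$pc, levels = 0:7),
               factor(table$npc, levels = 0:7))
  k <- matrix(as.numeric(tab), 8L, 8L,
              dimnames = list(paste0("PC", 0:7), paste0("NPC", 0:7)))
  rs <- rowSums(k)
  out <- k / ifelse(rs > 0, rs, NA_real_)
  out
}

#' Log-odds of the one-sided enrichment p-value
#'
#' A graded preference strength for a pair count: with
#' `q = P(X >= k)` under the null binomial, the value is
#' `-log(q / (1 - q))` — near 0 at the distribution median, large
#' positive for strong enrichment, strictly increasing in `k` at fixed
#' `(n, p)`.  Degenerate `q` in \{0, 1\} is clamped to `+-log(1e15)`.
#' Only monotonicity of this quantity is relied upon downstream (it feeds
#' the distance--preference correlation).
#'
#' @inheritParams binom_cdf
#' @return signed real.
#' @export
enrichment_log_odds <- function(k, n, p) {
  q <- binom_tail_upper(k, n, p)
  cap <- log(1e15)
  ifelse(q <= 0, cap,
         ifelse(q >= 1, -cap, pmin(cap, pmax(-cap, -log(q / (1 - q))))))
}

#' Per-image pair distance and preference strength
#'
#' Helper for the distance--preference correlation: for one image, the
#' mean nearest-neighbor distance over `(pc = i, npc = j)` pairs and the
#' enrichment log-odds of their count.
#'
#' @param dataset classified `image_dataset`.
#' @param table matching `nbr_table`.
#' @param i,j profile classes.
#' @return data frame with one row: `image_id`, `mean_dist`, `log_odds`,
#'   `n_pairs`; `mean_dist` is `NA` when the image has no such pair.
#' @export
pair_distance_logodds <- function(dataset, table, i = 0L, j = 0L) {
  f <- class_frequencies(dataset)
  sel <- table$pc == i & table$npc == j
  n_i <- sum(table$pc == i)
  k <- sum(sel)
  lo <- if (n_i > 0L) enrichment_log_odds(k, n_i, f[j + 1L]) else NA_real_
  data.frame(image_id = dataset$image_id,
             mean_dist = if (k > 0L) mean(table$nn_distance_um[sel]) else
               NA_real_,
             log_odds = lo,
             n_pairs = k)
}

#' Distance--preference Pearson correlation across images
#'
#' Sample Pearson correlation, across the images of a cohort, between the
#' mean `(i, j)`-pair nearest-neighbor distance and the enrichment
#' log-odds of the pair count.  A positive value says the preference is
#' strongest where the pairs sit far apart.
#'
#' @param stats data frame with columns `mean_dist` and `log_odds`
#'   (one row per image, e.g. rbind of [pair_distance_logodds()]), rows
#'   with `NA` dropped.
#' @return Pearson r; `NA` with a warning when fewer than 3 complete
#'   images or zero variance.
#' @export
distance_significance_correlation <- function(stats) {
  ok <- stats::complete.cases(stats[, c("mean_dist", "log_odds")])
  x <- stats$mean_dist[ok]
  y <- stats$log_odds[ok]
  if (length(x) < 3L) {
    warning("fewer than 3 images with defined values")
    return(NA_real_)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Write the per-image significance matrices to CSV
#'
#' Emits the published layout (NPC rows, PC columns) for the calls, plus
#' companion CSVs of the observed counts and the interval endpoints.
#'
#' @param sm a `significance_matrix`.
#' @param dir output directory.
#' @return paths of the four files, invisibly.
#' @export
write_significance_matrix <- function(sm, dir) {
  stopifnot(inherits(sm, "significance_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0("image_", sm$image_id))
  paths <- c(calls = paste0(stem, "_calls.csv"),
             k = paste0(stem, "_k.csv"),
             k_low = paste0(stem, "_klow.csv"),
             k_up = paste0(stem, "_kup.csv"))
  calls_out <- sm$calls
  calls_out[calls_out == "ns"] <- ""  # published layout leaves ns blank
  write_matrix(calls_out, paths["calls"])
  write_matrix(sm$k, paths["k"])
  write_matrix(sm$k_low, paths["k_low"])
  write_matrix(sm$k_up, paths["k_up"])
  invisible(paths)
}
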