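# Nearest-neighbor tables under the communication-distance cutoff, and
# distance statistics against the CSR closed form.

#' Build the nearest-neighbor table of an image
#'
#' For every classified cell, finds the other cell with minimal Euclidean
#' centroid distance.  Cells whose nearest other cell lies beyond the
#' cutoff are excluded from the table (but counted); the relation is
#' directional and need not be symmetric.  Distance ties are broken by the
#' lowest neighbor `cell_id`, so the table is deterministic.
#'
#' The default search uses a bucket grid of width `cutoff` with identical
#' output to the all-pairs scan (`method = "brute"`), which remains
#' available as an oracle.
#'
#' @param dataset an `image_dataset` with `pc` assigned.
#' @param cutoff maximal neighbor distance in um (default 175, i.e. 700
#'   pixels at 0.25 um/px).
#' @param method `"grid"` (default) or `"brute"`; results are identical.
#' @return a data frame of class `nbr_table` with columns
#'   `cell_id, pc, neighbor_id, npc, nn_distance_um`, and attribute
#'   `excluded_isolated` (count of cells with no neighbor within cutoff).
#' @export
nearest_neighbors <- function(dataset, cutoff = 175,
                              method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "image_dataset"), cutoff > 0)
  cells <- dataset$cells
  if (anyNA(cells$pc)) {
    stop("dataset contains unclassified cells (missing pc); ",
         "run classify_cells() first", call. = FALSE)
  }
  n <- nrow(cells)
  empty <- data.frame(cell_id = integer(0), pc = integer(0),
                      neighbor_id = integer(0), npc = integer(0),
                      nn_distance_um = numeric(0))
  if (n < 2L) {
    return(structure(empty, excluded_isolated = n, class =
                       c("nbr_table", "data.frame")))
  }
  x <- cells$x_um; y <- cells$y_um; id <- cells$cell_id
  nn_idx <- rep(NA_integer_, n)
  nn_d <- rep(Inf, n)
  if (method == "brute" || n <= 256L) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    diag(d) <- Inf
    for (i in seq_len(n)) {
      j <- which(d[i, ] == min(d[i, ]))
      j <- j[which.min(id[j])]
      nn_idx[i] <- j
      nn_d[i] <- d[i, j]
    }
  } else {
    bx <- as.integer(floor((x - min(x)) / cutoff))
    by <- as.integer(floor((y - min(y)) / cutoff))
    nbx <- max(bx) + 1L
    bucket_of <- bx + by * nbx
    members <- split(seq_len(n), bucket_of)
    keys <- as.integer(names(members))
    key_env <- new.env(hash = TRUE, size = length(members))
    for (k in seq_along(members)) {
      assign(as.character(keys[k]), members[[k]], envir = key_env)
    }
    for (k in seq_along(members)) {
      pts <- members[[k]]
      kb <- keys[k]
      kx <- kb %% nbx
      ky <- kb %/% nbx
      cand <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        cx <- kx + dx; cy <- ky + dy
        if (cx < 0 || cx >= nbx || cy < 0) next
        got <- get0(as.character(cx + cy * nbx), envir = key_env,
                    ifnotfound = NULL)
        if (!is.null(got)) cand <- c(cand, got)
      }
      dm <- outer(x[pts], x[cand], "-")^2 + outer(y[pts], y[cand], "-")^2
      self <- outer(pts, cand, "==")
      dm[self] <- Inf
      for (r in seq_along(pts)) {
        dmin <- min(dm[r, ])
        if (is.finite(dmin)) {
          j <- cand[dm[r, ] == dmin]
          j <- j[which.min(id[j])]
          nn_idx[pts[r]] <- j
          nn_d[pts[r]] <- sqrt(dmin)
        }
      }
    }
  }
  keep <- is.finite(nn_d) & nn_d <= cutoff
  out <- data.frame(cell_id = id[keep],
                    pc = cells$pc[keep],
                    neighbor_id = id[nn_idx[keep]],
                    npc = cells$pc[nn_idx[keep]],
                    nn_distance_um = nn_d[keep])
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, excluded_isolated = n - nrow(out),
            class = c("nbr_table", "data.frame"))
}

#' Write/read a neighborhood table CSV
#'
#' @param table an `nbr_table`.
#' @param path CSV path.
#' @export
write_nbr_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_nbr_table
#' @export
read_nbr_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "pc", "neighbor_id", "npc", "nn_distance_um")
  if (!all(need %in% names(df))) {
    stop("not a neighborhood table CSV (need columns ",
         paste(need, collapse = ", "), "): ", path, call. = FALSE)
  }
  structure(df[need], excluded_isolated = NA_integer_,
            class = c("nbr_table", "data.frame"))
}

#' Nearest-neighbor distance distribution under CSR
#'
#' For a homogeneous Poisson process of intensity `lambda`, the
#' nearest-neighbor distance has the Rayleigh density
#' `2 * pi * lambda * r * exp(-pi * lambda * r^2)` with mean
#' `1 / (2 * sqrt(lambda))`.  This is the reference the observed
#' distributions are compared against to detect clustering.
#'
#' @param lambda intensity in cells per um^2 (> 0).
#' @return list with functions `pdf(r)`, `cdf(r)`, and the closed-form
#'   `mean` (um).
#' @export
csr_nn_distribution <- function(lambda) {
  if (!(is.numeric(lambda) && length(lambda) == 1L && lambda > 0)) {
    stop("lambda must be a single positive intensity", call. = FALSE)
  }
  list(pdf = function(r) 2 * pi * lambda * r * exp(-pi * lambda * r^2),
       cdf = function(r) 1 - exp(-pi * lambda * r^2),
       mean = 1 / (2 * sqrt(lambda)))
}

#' Mean nearest-neighbor distance
#'
#' @param table an `nbr_table`.
#' @return named numeric `c(mean, sd)` in um (`sd` is 0 for a single row).
#' @export
mean_nn_distance <- function(table) {
  d <- table$nn_distance_um
  if (length(d) == 0L) stop("empty neighborhood table", call. = FALSE)
  c(mean = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0)
}

#' Distance ratio of same-class pairs to all pairs
#'
#' Ratio of the mean nearest-neighbor distance over rows with
#' `pc == npc == class` to the mean over all rows.  A ratio above 1 for
#' the small round class says its same-class pairs sit farther apart than
#' typical neighbors — the signature of preferential location in sparse
#' tissue regions rather than mutual attraction.
#'
#' @param table an `nbr_table`.
#' @param class profile class (default 0, small round).
#' @return the ratio, or `NA` (with a warning) when no qualifying pair
#'   exists.
#' @export
pc0_pair_distance_ratio <- function(table, class = 0L) {
  sel <- table$pc == class & table$npc == class
  if (!any(sel)) {
    warning("no (pc = ", class, ", npc = ", class, ") pairs in table")
    return(NA_real_)
  }
  mean(table$nn_distance_um[sel]) / mean(table$nn_distance_um)
}
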