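# Shared fixtures and independent oracles used across the suite.

# A well-formed random cell table (classifier-consistent morphology not
# required unless classify = TRUE).
make_cells <- function(n, window = c(0, 500, 0, 500), classify = FALSE,
                       pc_prob = rep(1 / 8, 8)) {
  pc <- sample(0:7, n, replace = TRUE, prob = pc_prob)
  if (classify) {
    m <- cd30nbhd:::sample_morphology(pc, threshold_config())
  } else {
    area <- runif(n, 120, 1500)
    m <- data.frame(area_um2 = area,
                    eccentricity = runif(n, 0, 0.99),
                    solidity = runif(n, 0.6, 1),
                    feret_um = equivalent_disk_diameter(area) *
                      runif(n, 1.01, 1.6))
  }
  data.frame(cell_id = seq_len(n),
             x_um = runif(n, window[1], window[2]),
             y_um = runif(n, window[3], window[4]),
             m, pc = pc)
}

make_dataset <- function(n, ..., image_id = "t", diagnosis = "LA",
                         window = c(0, 500, 0, 500)) {
  image_dataset(make_cells(n, window = window, ...), image_id, diagnosis,
                window = window)
}

# Neighborhood table as a plain data frame (drops class and bookkeeping
# attributes) for content comparisons.
as_plain <- function(tab) {
  out <- as.data.frame(tab)
  attr(out, "excluded_isolated") <- NULL
  rownames(out) <- NULL
  out
}

# Brute-force all-pairs nearest-neighbor oracle (independent of the
# package's grid path; plain loops).
brute_nn <- function(cells, cutoff) {
  n <- nrow(cells)
  rows <- list()
  iso <- 0L
  for (i in seq_len(n)) {
    best_d <- Inf
    best_j <- NA_integer_
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                (cells$y_um[i] - cells$y_um[j])^2)
      if (d < best_d ||
          (d == best_d && cells$cell_id[j] < cells$cell_id[best_j])) {
        best_d <- d
        best_j <- j
      }
    }
    if (is.finite(best_d) && best_d <= cutoff) {
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = cells$cell_id[i], pc = cells$pc[i],
                   neighbor_id = cells$cell_id[best_j],
                   npc = cells$pc[best_j], nn_distance_um = best_d)
    } else {
      iso <- iso + 1L
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  list(table = out, excluded = iso)
}

# Term-by-term binomial tail oracle (independent of pbinom's incomplete
# beta): exhaustive scan of all k for the prediction-interval endpoints.
brute_interval <- function(n, p, alpha) {
  terms <- choose(n, 0:n) * p^(0:n) * (1 - p)^(n - (0:n))
  cdf <- cumsum(terms)
  upper <- rev(cumsum(rev(terms)))
  half <- alpha / 2
  lows <- which(cdf <= half)
  ups <- which(upper <= half)
  c(k_low = if (length(lows) > 0) max(lows) - 1 else -1,
    k_up = if (length(ups) > 0) min(ups) - 1 else n + 1)
}

# Random 8-connected pixel blob by random walk, as a mask_image.
rand_blob <- function(n_px = 150, resolution = 0.25, size = 64L) {
  lab <- matrix(0L, size, size)
  r <- size %/% 2L
  c0 <- size %/% 2L
  lab[r, c0] <- 1L
  placed <- 1L
  while (placed < n_px) {
    step <- sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
    r2 <- min(max(r + step[1], 2L), size - 1L)
    c2 <- min(max(c0 + step[2], 2L), size - 1L)
    if (lab[r2, c2] == 0L) {
      lab[r2, c2] <- 1L
      placed <- placed + 1L
    }
    r <- r2
    c0 <- c2
  }
  structure(list(labels = lab, resolution = resolution, origin = c(0, 0)),
            class = "mask_image")
}

study_fractions <- c(0.386, 0.047, 0.130, 0.008,
                     0.255, 0.040, 0.104, 0.030)

# Study-like null: CSR positions, class labels independent of positions.
null_spec <- function(total_intensity = 5e-4) {
  synthetic_spec(window = c(0, 2000, 0, 2000),
                 intensity = total_intensity * study_fractions,
                 clustering = NULL)
}

# Dense miniature cohort spec for structural tests: a small window at
# whole-slide class fractions, tightly clustered so images stay small but
# populated.
dense_spec <- function(window = c(0, 800, 0, 800), total_intensity = 2e-3,
                       ...) {
  intensity <- total_intensity * study_fractions
  synthetic_spec(window = window, intensity = intensity,
                 clustering = default_clustering(intensity,
                                                 offspring_mean = 20,
                                                 sigma = 25),
                 ...)
}
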