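test_that("binomial CDF: closed forms, domain checks, and summation oracle", {
  expect_equal(binom_cdf(0, 10, 0.5), 1 / 1024)
  expect_equal(binom_cdf(10, 10, 0.5), 1)
  expect_equal(binom_tail_upper(0, 5, 0.3), 1)
  expect_error(binom_cdf(-1, 10, 0.5), "k")
  expect_error(binom_cdf(3, 10, 1.5), "p")

  set.seed(51)
  for (r in 1:200) {
    n <- sample(0:200, 1)
    k <- if (n > 0) sample(0:n, 1) else 0
    p <- runif(1)
    terms <- choose(n, 0:n) * p^(0:n) * (1 - p)^(n - (0:n))
    expect_equal(binom_cdf(k, n, p), sum(terms[seq_len(k + 1)]),
                 tolerance = 1e-12)
    expect_equal(binom_tail_upper(k, n, p), sum(terms[(k + 1):(n + 1)]),
                 tolerance = 1e-12)
  }
})

test_that("prediction interval endpoints match the exhaustive-scan oracle", {
  pi1 <- prediction_interval(10, 0.5, 0.01)
  expect_equal(c(pi1$k_low, pi1$k_up), c(0, 10))
  # CDF(0) = 1/1024 <= 0.005 but CDF(1) = 11/1024 > 0.005

  set.seed(52)
  for (r in 1:300) {
    n <- sample(0:200, 1)
    p <- runif(1)
    alpha <- runif(1, 0.001, 0.2)
    got <- prediction_interval(n, p, alpha)
    ref <- brute_interval(n, p, alpha)
    expect_equal(c(got$k_low, got$k_up), unname(ref))
  }

  # degenerate probabilities
  p0 <- prediction_interval(20, 0, 0.01)
  expect_equal(p0$k_low, -1)
  expect_equal(p0$k_up, 1)
  p1 <- prediction_interval(20, 1, 0.01)
  expect_equal(p1$k_low, 19)
  expect_equal(p1$k_up, 21)
  expect_error(prediction_interval(10, 0.5, 0), "alpha")
  expect_error(prediction_interval(10, 1.5, 0.01), "p")
})

test_that("shrinking alpha never narrows the interval", {
  set.seed(53)
  for (r in 1:30) {
    n <- sample(10:500, 1)
    p <- runif(1, 0.05, 0.95)
    wide <- prediction_interval(n, p, 0.001)
    narrow <- prediction_interval(n, p, 0.05)
    expect_lte(wide$k_low, narrow$k_low)
    expect_gte(wide$k_up, narrow$k_up)
  }
})

test_that("significance calls: worked example is sh, endpoints are ns", {
  # image 1721: n = 3,435 small round cells, f(0) = 3,435/10,860,
  # observed k = 1,217 same-class pairs
  pint <- prediction_interval(3435, 3435 / 10860, 0.01)
  expect_identical(significance_call(1217, pint), "sh")
  expect_identical(significance_call(pint$k_low, pint), "ns")
  expect_identical(significance_call(pint$k_up, pint), "ns")
  expect_identical(significance_call(pint$k_low + 1, pint), "ns")
  expect_identical(significance_call(max(0, pint$k_low - 1), pint), "sl")
})

test_that("interval coverage at the worked example's size is within level", {
  set.seed(54)
  pint <- prediction_interval(3435, 0.316, 0.01)
  draws <- rbinom(1e4, 3435, 0.316)
  outside <- mean(draws < pint$k_low | draws > pint$k_up)
  expect_lte(outside, 0.012)
})

make_point_ds_sig <- function(n) {
  cells <- data.frame(cell_id = seq_len(n),
                      x_um = runif(n, 0, 200), y_um = runif(n, 0, 200),
                      area_um2 = 200, eccentricity = 0.2, solidity = 0.95,
                      feret_um = 17, pc = 0L)
  image_dataset(cells, "solo", "LA")
}

test_that("significance_matrix wires n, k, p correctly and handles degenerates", {
  set.seed(55)
  ds <- make_dataset(600)
  tab <- nearest_neighbors(ds, 175)
  sm <- significance_matrix(ds, tab, 0.01)
  f <- class_frequencies(ds)
  expect_equal(unname(sm$p), unname(f))
  expect_equal(unname(sm$n), unname(tabulate(tab$pc + 1L, 8L)))
  expect_equal(unname(rowSums(sm$k)), as.numeric(sm$n))
  for (i in 0:7) for (j in 0:7) {
    expect_equal(sm$k[i + 1, j + 1],
                 sum(tab$pc == i & tab$npc == j))
  }
  # calls consistent with k against the recorded interval
  above <- sm$k > sm$k_up
  below <- sm$k < sm$k_low
  expect_true(all(sm$calls[above] == "sh"))
  expect_true(all(sm$calls[below] == "sl"))
  expect_true(all(sm$calls[!above & !below] == "ns"))

  # single-class image: p = 1 for that class, everything ns
  solo <- make_point_ds_sig(50)
  tab1 <- nearest_neighbors(solo, 175)
  sm1 <- significance_matrix(solo, tab1)
  expect_true(all(sm1$calls == "ns"))
})

test_that("conditional probabilities: worked example and row conservation", {
  expect_equal(round(1217 / 3435, 3), 0.354)
  tab <- structure(data.frame(cell_id = 1:3, pc = c(0L, 0L, 4L),
                              neighbor_id = c(2L, 3L, 1L),
                              npc = c(0L, 4L, 0L),
                              nn_distance_um = c(10, 20, 30)),
                   class = c("nbr_table", "data.frame"))
  cp <- conditional_probabilities(tab)
  expect_equal(cp["PC0", "NPC0"], 0.5)
  expect_equal(cp["PC0", "NPC4"], 0.5)
  expect_equal(cp["PC4", "NPC0"], 1)
  expect_true(all(is.na(cp["PC1", ])))

  set.seed(56)
  for (r in 1:5) {
    ds <- make_dataset(400)
    cp <- conditional_probabilities(nearest_neighbors(ds))
    sums <- rowSums(cp)
    expect_equal(unname(sums[!is.na(sums)]),
                 rep(1, sum(!is.na(sums))))
  }
})

test_that("enrichment log-odds is monotone in k, ~0 at the median, clamped", {
  v <- enrichment_log_odds(0:50, 50, 0.4)
  expect_true(all(diff(v) >= 0))
  # strictly increasing wherever the value is not clamped
  cap <- log(1e15)
  unclamped <- abs(v) < cap
  expect_true(all(diff(v[unclamped]) > 0))
  med <- qbinom(0.5, 50, 0.4)
  expect_lt(abs(enrichment_log_odds(med, 50, 0.4)), 0.5)
  expect_gt(enrichment_log_odds(20, 20, 0.5), 5)
  expect_equal(enrichment_log_odds(0, 50, 1e-12), -log(1e15),
               tolerance = 1e-6)
})

test_that("distance-preference correlation: linear, null, affine-invariant", {
  lin <- data.frame(mean_dist = 1:10, log_odds = 2 * (1:10) + 3)
  expect_equal(distance_significance_correlation(lin), 1)

  set.seed(57)
  nul <- data.frame(mean_dist = rnorm(1000), log_odds = rnorm(1000))
  expect_lt(abs(distance_significance_correlation(nul)), 0.1)

  mix <- data.frame(mean_dist = runif(30, 20, 60),
                    log_odds = rnorm(30))
  r0 <- distance_significance_correlation(mix)
  mix2 <- data.frame(mean_dist = 5 * mix$mean_dist - 7,
                     log_odds = 0.1 * mix$log_odds + 2)
  expect_equal(distance_significance_correlation(mix2), r0)

  expect_warning(r <- distance_significance_correlation(
    data.frame(mean_dist = c(1, 2), log_odds = c(1, 2))), "fewer")
  expect_true(is.na(r))
  expect_warning(r2 <- distance_significance_correlation(
    data.frame(mean_dist = c(1, 1, 1), log_odds = c(1, 2, 3))), "variance")
  expect_true(is.na(r2))
})

test_that("shuffling labels destroys planted calls (permutation soundness)", {
  att <- synthetic_spec(attraction_pairs = data.frame(a = 5, b = 7,
                                                      fraction = 0.8))
  set.seed(58)
  coh <- sample_preferential_cohort(att, n_images = 1, diagnoses = "NScHL",
                                    seed = 99)
  ds <- coh$datasets[[1]]
  sm <- significance_matrix(ds, nearest_neighbors(ds))
  expect_identical(sm$calls["PC7", "NPC5"], "sh")

  rates <- numeric(20)
  for (r in 1:20) {
    shuf <- ds
    shuf$cells$pc <- sample(shuf$cells$pc)
    sm_s <- significance_matrix(shuf, nearest_neighbors(shuf))
    rates[r] <- mean(sm_s$calls != "ns")
  }
  expect_lt(mean(rates), 0.05)  # planted structure gone, calls near alpha
})

test_that("optional BH adjustment only removes calls", {
  set.seed(59)
  ds <- make_dataset(800)
  tab <- nearest_neighbors(ds)
  plain <- significance_matrix(ds, tab, 0.05)
  adj <- significance_matrix(ds, tab, 0.05, adjust = "BH")
  expect_true(all(adj$calls[plain$calls == "ns"] == "ns"))
})
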