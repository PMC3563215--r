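test_that("bandwidth schemes follow their length functions", {
  expect_equal(compute_bandwidth(300, "linear:15"), 20)
  expect_equal(compute_bandwidth(100, "power:2"), 10)
  expect_equal(compute_bandwidth(256, "log:2"), 8)
  expect_equal(compute_bandwidth(123, "fixed:5"), 5)
  expect_error(compute_bandwidth(1, "log:2"), "non-positive")
  expect_error(compute_bandwidth(100, "log:1"), "base > 1")
  expect_error(compute_bandwidth(100, "fixed:-3"), "positive")
  expect_error(compute_bandwidth(100, "amise"), "contact list")
})

test_that("amise bandwidth is positive and responds to profile spread", {
  sim <- generate_multidomain_contacts(sim_spec(c(60, 60)), seed = 3)
  h <- compute_bandwidth(sim$contacts$length, "amise", contacts = sim$contacts)
  expect_true(is.finite(h) && h > 0 && h < sim$contacts$length)
})

test_that("a single short-range contact concentrates mass at the residue between", {
  cl <- contact_list(data.frame(i = 10, j = 12, score = 1), length = 20)
  prof <- contact_cut_profile(cl, sigma = 0.5)
  expect_equal(which.max(prof), 11L)
  expect_equal(sum(prof), 1, tolerance = 1e-9)
})

test_that("profile matches the triple-loop oracle and normalizes to unit sum", {
  set.seed(11)
  for (rep in 1:5) {
    L <- sample(30:120, 1)
    n <- sample(20:200, 1)
    i <- sample(1:(L - 6), n, replace = TRUE)
    j <- pmin(i + sample(2:40, n, replace = TRUE), L)
    df <- data.frame(i = i, j = j, score = runif(n))
    df <- df[!duplicated(paste(df$i, df$j)) & df$j > df$i, ]
    cl <- contact_list(df, length = L)
    sigma <- runif(1, 1, 15)
    prof <- contact_cut_profile(cl, sigma)
    expect_equal(as.numeric(prof), profile_oracle(cl, sigma), tolerance = 1e-9)
    expect_equal(sum(prof), 1, tolerance = 1e-9)
    expect_true(all(prof >= 0))
  }
})

test_that("separation-1 contacts contribute nothing; all-such lists are an error", {
  cl <- contact_list(data.frame(i = c(10, 30), j = c(11, 40),
                                score = c(0.9, 0.5)), length = 50)
  prof <- contact_cut_profile(cl, sigma = 2)
  only_far <- contact_list(data.frame(i = 30, j = 40, score = 0.5), length = 50)
  expect_equal(as.numeric(prof),
               as.numeric(contact_cut_profile(only_far, sigma = 2)))
  adj <- contact_list(data.frame(i = 10, j = 11, score = 1), length = 50)
  expect_error(contact_cut_profile(adj, sigma = 2), "separation")
  empty <- filter_contacts(adj, min_sep = 5)
  expect_error(contact_cut_profile(empty, sigma = 2), "no contacts")
})

test_that("windowed slope has the right sign on monotone, flat and V-shaped profiles", {
  incr <- seq(0.01, 1, length.out = 50)
  expect_true(all(estimate_slope(incr, 2:49) > 0))
  flat <- rep(0.02, 50)
  expect_equal(estimate_slope(flat, 1:50), rep(0, 50), tolerance = 1e-12)
  v <- abs(seq_len(50) - 25)
  expect_lt(estimate_slope(v, 24), 0)
  expect_gt(estimate_slope(v, 26), 0)
  # central-difference alternative agrees in sign
  expect_lt(estimate_slope(v, 24, method = "central"), 0)
  expect_gt(estimate_slope(v, 26, method = "central"), 0)
})

test_that("cut points sit at profile minima: unimodal none, bimodal trough, flat none", {
  x <- 1:99
  unimodal <- dnorm(x, 50, 15)
  expect_length(find_cut_points(unimodal), 0L)
  bimodal <- dnorm(x, 25, 10) + dnorm(x, 75, 10)
  expect_equal(find_cut_points(bimodal), 50L)
  expect_length(find_cut_points(rep(0.5, 99)), 0L)
})

test_that("plateau minima report the central position", {
  # piecewise-linear: descend to a flat valley over 41-50, then ascend
  prof <- c(seq(10, 1, length.out = 40), rep(1, 10), seq(1, 10, length.out = 40))
  cuts <- find_cut_points(prof)
  expect_length(cuts, 1L)
  expect_true(abs(cuts - 45L) <= 1L)
})

test_that("dense two-block contacts give a boundary trough near the split", {
  cl <- two_block_contacts(L = 100, split = 50)
  prof <- contact_cut_profile(cl, sigma = 100 / 15)
  cuts <- find_cut_points(prof)
  expect_true(any(cuts >= 48 & cuts <= 53))
  # trough confirmed by the independent oracle profile
  oprof <- profile_oracle(cl, 100 / 15)
  expect_equal(as.numeric(prof), oprof, tolerance = 1e-9)
  expect_lt(min(oprof[48:53]), min(oprof[25], oprof[75]))
})

test_that("the full KDE pipeline recovers a clean two-domain split", {
  sim <- generate_multidomain_contacts(
    sim_spec(c(60, 60), p_inter = 0, noise_frac = 0), seed = 1)
  pred <- predict_domains_kde(sim$contacts)
  expect_equal(n_domains(pred), 2L)
  expect_lte(abs(pred$cuts[1] - 61L), 2L)
  # segments partition 1..L exactly once
  lab <- label_residues(pred)
  expect_false(anyNA(lab))
  expect_equal(sort(unique(lab)), 1:2)
})

test_that("a single compact domain yields one full-length domain", {
  sim <- generate_multidomain_contacts(
    sim_spec(c(80), noise_frac = 0), seed = 2)
  pred <- predict_domains_kde(sim$contacts)
  expect_equal(format_chopping(pred), "1-80")
})

test_that("undersmoothing predicts at least as many domains as oversmoothing", {
  sim <- generate_multidomain_contacts(sim_spec(c(60, 60)), seed = 5)
  p1 <- predict_domains_kde(sim$contacts, bandwidth = "fixed:1")
  p50 <- predict_domains_kde(sim$contacts, bandwidth = "fixed:50")
  expect_gte(n_domains(p1), n_domains(p50))
})

test_that("empty filtered contact lists yield a single-domain prediction with warning", {
  cl <- contact_list(data.frame(i = 1:5, j = 3:7, score = runif(5)), length = 90)
  expect_warning(pred <- predict_domains_kde(cl), "single-domain")
  expect_equal(format_chopping(pred), "1-90")
})

test_that("profiles and cut points are shift-equivariant", {
  base_df <- data.frame(i = c(30, 35, 40, 70, 75, 62),
                        j = c(45, 50, 55, 90, 95, 80), score = 1)
  t <- 17L
  cl0 <- contact_list(base_df, length = 130)
  cl1 <- contact_list(transform(base_df, i = i + t, j = j + t), length = 130 + t)
  p0 <- contact_cut_profile(cl0, sigma = 3)
  p1 <- contact_cut_profile(cl1, sigma = 3)
  expect_equal(as.numeric(p1[(1 + t):(130 + t)]), as.numeric(p0),
               tolerance = 1e-9)
  expect_equal(find_cut_points(p1), find_cut_points(p0) + t)
})

test_that("predicted segments always partition the chain", {
  targets <- generate_benchmark_set(10, seed = 15, n_domains = 1:4,
                                    domain_length = c(40, 80))
  for (tg in targets) {
    pred <- predict_domains_kde(tg$contacts)
    lab <- label_residues(pred)
    expect_false(anyNA(lab))
    expect_equal(sort(unique(lab)), seq_len(n_domains(pred)))
  }
})

test_that("clean-signal boundary recovery is high and bit-reproducible", {
  mk <- function() generate_benchmark_set(
    30, seed = 123, spec_args = list(p_inter = 0, noise_frac = 0))
  rate <- boundary_recovery(mk())
  expect_gte(rate, 0.8)
  expect_identical(mk(), mk())
})

test_that("min_domain merges segments shorter than the floor", {
  prof_cl <- two_block_contacts(L = 100, split = 50)
  pred <- predict_domains_kde(prof_cl, bandwidth = "fixed:5", min_domain = 60)
  expect_equal(format_chopping(pred), "1-100")
})
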