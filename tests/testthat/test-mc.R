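test_that("the absorption fraction follows the bounded Kow model", {
  expect_equal(f_abs(0), 1 / (1.11e-8 + 0.41 + 1.01), tolerance = 1e-12)
  expect_equal(round(f_abs(0), 4), 0.7042)
  # analytic maximum at Kow = sqrt(0.41 / 1.11e-8)
  k_star <- log10(sqrt(0.41 / 1.11e-8))
  expect_equal(f_abs(k_star),
               1 / (2 * sqrt(0.41 * 1.11e-8) + 1.01), tolerance = 1e-12)
  expect_equal(round(f_abs(k_star), 5), 0.98997)
  expect_true(all(f_abs(seq(-6, 25, by = 0.5)) <= f_abs(k_star)))
  # extreme lipophilicity drives absorption towards zero
  expect_lt(f_abs(25), 1e-8)
  expect_true(all(f_abs(c(-10, 0, 5, 20)) > 0))
  expect_error(f_abs(Inf), "finite")
})

test_that("distribution sampling is reproducible and respects truncation", {
  expect_equal(sample_dist(dist_spec("point", value = 2.5), 4),
               rep(2.5, 4))
  u <- sample_dist(dist_spec("uniform", min = 0, max = 1), 1e4, seed = 5)
  expect_lt(abs(mean(u) - 0.5), 0.02)  # 3-sigma CLT band ~ 0.0087
  tr <- dist_spec("lognormal", meanlog = 0, sdlog = 1,
                  truncation = c(0.5, 2))
  d <- sample_dist(tr, 2000, seed = 5)
  expect_true(all(d >= 0.5 & d <= 2))
  expect_equal(sample_dist(tr, 50, seed = 9), sample_dist(tr, 50, seed = 9))
  # zero-mass truncation errors after the rejection cap
  bad <- dist_spec("uniform", min = 0, max = 1, truncation = c(5, 6))
  expect_error(sample_dist(bad, 10, seed = 1, max_rounds = 5),
               "infeasible")
  tri <- sample_dist(dist_spec("triangular", min = 0, mode = 1, max = 4),
                     1e4, seed = 5)
  expect_true(all(tri >= 0 & tri <= 4))
  expect_lt(abs(mean(tri) - 5 / 3), 0.03)  # (min+mode+max)/3
  expect_error(dist_spec("point", value = c(1, 2)), "exactly one")
  expect_error(dist_spec("triangular", min = 2, mode = 1, max = 4),
               "min <= mode <= max")
})

test_that("draw profiles use linear-interpolation percentiles", {
  p <- summarize_draws(1:100)
  expect_equal(unname(p["p50"]), 50.5)
  expect_equal(unname(p["mean"]), 50.5)
  expect_equal(unname(p["p5"]), stats::quantile(1:100, 0.05, names = FALSE))
  expect_equal(unname(p["max"]), 100)
  expect_equal(summarize_draws(rep(3, 10)),
               stats::setNames(rep(3, 8),
                               c("mean", "p5", "p50", "p75", "p90", "p95",
                                 "p99", "max")))
  shuffled <- sample(1:100)
  expect_equal(summarize_draws(shuffled), summarize_draws(1:100))
  expect_error(summarize_draws(numeric()), "no draws")
})

test_that("degenerate point distributions match the closed form", {
  m <- point_model(c_value = 0.1, rfd = 1, n_iter = 500, seed = 2)
  closed <- 0.1 * 1 * 1 * 365 / (365 * 60.95)
  expect_true(all(abs(m$draws$edi - closed) <= 1e-12 * closed))
  expect_true(all(abs(unlist(m$profile["edi", ]) - closed) <=
                    1e-12 * closed))
  expect_true(is.na(m$hq_exceeds_1_at))
  # zero concentration: everything is zero, nothing flagged
  z <- point_model(c_value = 0, rfd = 1, n_iter = 100, seed = 2)
  expect_true(all(z$draws$edi == 0))
  expect_true(all(z$draws$hq == 0))
  expect_true(is.na(z$hq_exceeds_1_at))
})

test_that("the HQ profile is the EDI profile divided by the RfD", {
  m <- mc_exposure(
    c_spec = dist_spec("lognormal", meanlog = log(0.2), sdlog = 1),
    fc_spec = dist_spec("triangular", min = 0.5, mode = 1, max = 2),
    ef_spec = dist_spec("point", value = 350),
    bw_spec = dist_spec("normal", mean = 60.95, sd = 10,
                        truncation = c(40, 120)),
    fabs = 1, rfd = 0.009, n_iter = 5000, seed = 31)
  expect_equal(m$draws$hq, m$draws$edi / 0.009)
  expect_equal(as.numeric(m$profile["hq", ]),
               as.numeric(m$profile["edi", ]) / 0.009)
  # at RfD = 1 the two profiles are numerically identical
  m1 <- mc_exposure(
    c_spec = dist_spec("lognormal", meanlog = log(0.2), sdlog = 1),
    fc_spec = dist_spec("point", value = 1),
    ef_spec = dist_spec("point", value = 365),
    bw_spec = dist_spec("point", value = 60.95),
    fabs = 1, rfd = 1, n_iter = 10000, seed = 31)
  expect_identical(as.numeric(m1$profile["hq", ]),
                   as.numeric(m1$profile["edi", ]))
})

test_that("percentiles are monotone and runs are seed-reproducible", {
  specs <- list(
    dist_spec("lognormal", meanlog = -2, sdlog = 1.5),
    dist_spec("uniform", min = 0, max = 0.5),
    dist_spec("empirical", values = c(0, 0, 0.01, 0.2, 1.3)))
  for (cs in specs) {
    m <- mc_exposure(cs, dist_spec("triangular", min = 0.5, mode = 1,
                                   max = 2),
                     dist_spec("point", value = 350),
                     dist_spec("normal", mean = 60.95, sd = 10,
                               truncation = c(40, 120)),
                     log_kow = 4.9, rfd = 0.03, n_iter = 2000, seed = 17)
    prof <- unlist(m$profile["edi", c("p5", "p50", "p75", "p90", "p95",
                                      "p99", "max")])
    expect_true(all(diff(prof) >= 0))
    again <- mc_exposure(cs, dist_spec("triangular", min = 0.5, mode = 1,
                                       max = 2),
                         dist_spec("point", value = 350),
                         dist_spec("normal", mean = 60.95, sd = 10,
                                   truncation = c(40, 120)),
                         log_kow = 4.9, rfd = 0.03, n_iter = 2000,
                         seed = 17)
    expect_identical(m$profile, again$profile)
  }
})

test_that("the profile is multiplicatively linear in the concentration", {
  base_args <- list(fc_spec = dist_spec("triangular", min = 0.5, mode = 1,
                                        max = 2),
                    ef_spec = dist_spec("point", value = 350),
                    bw_spec = dist_spec("normal", mean = 60.95, sd = 10,
                                        truncation = c(40, 120)),
                    fabs = 0.7, rfd = 0.009, n_iter = 4000, seed = 23)
  k <- 3.7
  m1 <- do.call(mc_exposure, c(list(
    c_spec = dist_spec("lognormal", meanlog = log(0.1), sdlog = 1)),
    base_args))
  mk <- do.call(mc_exposure, c(list(
    c_spec = dist_spec("lognormal", meanlog = log(0.1) + log(k),
                       sdlog = 1)), base_args))
  expect_equal(as.matrix(mk$profile), k * as.matrix(m1$profile),
               tolerance = 1e-12)
})

test_that("exposure duration cancels: ED never moves the profile", {
  args <- list(c_spec = dist_spec("lognormal", meanlog = -2, sdlog = 1),
               fc_spec = dist_spec("point", value = 1),
               ef_spec = dist_spec("point", value = 365),
               bw_spec = dist_spec("point", value = 60.95),
               fabs = 1, rfd = 1, n_iter = 3000, seed = 41)
  m_a <- do.call(mc_exposure, c(args, list(
    ed_spec = dist_spec("point", value = 30))))
  m_b <- do.call(mc_exposure, c(args, list(
    ed_spec = dist_spec("uniform", min = 1, max = 70))))
  m_c <- do.call(mc_exposure, args)  # no ED at all
  expect_identical(m_a$profile, m_b$profile)
  expect_identical(m_a$profile, m_c$profile)
})

test_that("profile means are stable across seeds at n = 10000", {
  runs <- vapply(1:6, function(s)
    unlist(mc_exposure(
      c_spec = dist_spec("lognormal", meanlog = log(0.1), sdlog = 1),
      fc_spec = dist_spec("point", value = 1),
      ef_spec = dist_spec("point", value = 365),
      bw_spec = dist_spec("point", value = 60.95),
      fabs = 1, rfd = 1, n_iter = 10000, seed = 100 + s)$profile[
        "edi", "mean"]),
    numeric(1))
  # lognormal(log 0.1, 1): E = 0.1 e^{1/2}; SEM = sd/sqrt(n)
  true_mean <- 0.1 * exp(0.5) / 60.95
  sem <- 0.1 * exp(0.5) * sqrt(exp(1) - 1) / 60.95 / sqrt(10000)
  expect_true(all(abs(runs - true_mean) < 3 * sem))
})

test_that("model object methods expose the simulation coherently", {
  m <- point_model(c_value = 0.1, rfd = 0.001, n_iter = 200, seed = 4)
  expect_s3_class(m, "mc_exposure")
  expect_output(print(m), "Monte Carlo exposure")
  expect_output(print(summary(m)), "Exposure profile")
  expect_equal(unname(quantile(m, 0.5)), 0.1 / 60.95)
  df <- as.data.frame(m)
  expect_equal(df$metric, c("edi", "hq"))
  # HQ = EDI/0.001 > 1 everywhere: flagged from the lowest percentile
  expect_equal(m$hq_exceeds_1_at, "p5")
  pdf_file <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  plot(m)
  grDevices::dev.off()
  expect_true(file.size(pdf_file) > 0)
  expect_error(mc_exposure(dist_spec("point", value = 1),
                           dist_spec("point", value = 1),
                           dist_spec("point", value = 365),
                           dist_spec("point", value = 60),
                           fabs = 1, rfd = 1, n_iter = 10),
               "seed")
})
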