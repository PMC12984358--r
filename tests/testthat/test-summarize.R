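test_that("nd-as-zero summaries reproduce a single-detection group", {
  # 15 starch samples, one detection at 0.6e-3 mg/kg
  m <- make_measurements(c(0.0006, rep(NA, 14)),
                         censored = c(FALSE, rep(TRUE, 14)),
                         analyte_id = "irganox_245")
  s <- summarize_migration(m, convention = "table2_style")
  expect_equal(s$convention, "nd_as_zero")
  expect_equal(s$n, 15L)
  expect_equal(s$mean, 0.0006 / 15)      # 0.04e-3 mg/kg
  expect_equal(s$max, 0.0006)
  expect_equal(s$median, 0)
  expect_equal(s$detection_rate, 100 / 15)
})

test_that("detected-only summaries reproduce the soybean-oil means", {
  oil <- fixture_oil()
  s <- summarize_migration(oil, convention = "table3_style")
  s1010 <- s[s$analyte_id == "irganox_1010", ]
  expect_equal(s1010$n_detected, 7L)
  expect_equal(s1010$mean, 0.3431, tolerance = 1e-3)  # 343.1e-3 mg/kg
  expect_equal(s1010$max, 0.6037)
  jx <- s[s$analyte_id == "antioxidant_jx35", ]
  expect_equal(jx$detection_rate, 87.5)
  expect_equal(jx$max, 0.0254)
  # an all-ND analyte has undefined detected-only statistics, DR 0
  i168 <- s[s$analyte_id == "irgafos_168", ]
  expect_true(is.na(i168$mean))
  expect_equal(i168$detection_rate, 0)
})

test_that("an all-ND group under nd_as_zero is zero with DR 0", {
  m <- make_measurements(rep(NA, 14), censored = rep(TRUE, 14),
                         material_class = "fiber")
  s <- summarize_migration(m, convention = "nd_as_zero")
  expect_equal(s$mean, 0)
  expect_equal(s$max, 0)
  expect_equal(s$detection_rate, 0)
  expect_error(summarize_migration(m[0, ], convention = "nd_as_zero"),
               "empty")
})

test_that("summary invariants hold on generated data", {
  cfg <- tableware_generator_config()
  dat <- simulate_migration(cfg, seed = 11)
  s <- summarize_migration(dat, by = c("material_class", "analyte_id"),
                           convention = "nd_as_zero")
  expect_true(all(s$mean >= 0))
  expect_true(all(s$mean <= s$max + 1e-12))
  expect_true(all(s$max >= s$median))
  expect_true(all(s$detection_rate >= 0 & s$detection_rate <= 100))
  expect_true(all(s$sd >= 0))
  # monotonicity: raising one detected value weakly raises mean and max
  idx <- which(!dat$censored)[1]
  dat2 <- dat
  dat2$concentration_mg_per_kg[idx] <-
    dat2$concentration_mg_per_kg[idx] * 10
  s2 <- summarize_migration(dat2, by = c("material_class", "analyte_id"),
                            convention = "nd_as_zero")
  expect_true(all(s2$mean >= s$mean))
  expect_true(all(s2$max >= s$max))
})

test_that("pooled means match the stratified survey total column", {
  eth <- fixture_ethanol_summary()
  cls <- eth[eth$group != "total" & eth$analyte_id == "irganox_1010", ]
  pm <- pooled_mean(cls)
  expect_equal(pm$mean, (10 * 0.3529 + 15 * 0.5305 + 14 * 0) / 39)
  expect_equal(round(pm$mean * 1000, 1), 294.5)
  # identity cases
  one <- cls[2, ]
  expect_equal(pooled_mean(one)$mean, one$mean)
  eq <- data.frame(analyte_id = "x", mean = c(2, 2), n = c(5, 5),
                   n_detected = c(3, 3), convention = "nd_as_zero")
  expect_equal(pooled_mean(eq)$mean, 2)
  # mixing conventions is refused
  bad <- cls
  bad$convention[1] <- "detected_only"
  expect_error(pooled_mean(bad), "different conventions")
})

test_that("pooling equals summarising the concatenated groups", {
  set.seed(42)
  groups <- lapply(c(PLA = 4L, starch = 6L), function(n) {
    cens <- stats::runif(n) < 0.4
    make_measurements(ifelse(cens, NA, stats::runif(n)), cens)
  })
  groups$PLA$material_class <- "PLA"
  groups$PLA$sample_id <- paste0("p", seq_len(4))
  all_m <- as_migration_data(rbind(as.data.frame(groups$PLA),
                                   as.data.frame(groups$starch)))
  by_class <- summarize_migration(all_m,
                                  by = c("material_class", "analyte_id"),
                                  convention = "nd_as_zero")
  pooled <- pooled_mean(by_class)
  direct <- summarize_migration(all_m, by = "analyte_id",
                                convention = "nd_as_zero")
  expect_equal(pooled$mean, direct$mean)
  expect_equal(pooled$n, direct$n)
})

test_that("detection rates count samples or cells as requested", {
  # 39 samples, 20 with at least one detection
  cens <- rep(c(FALSE, TRUE), c(20, 19))
  m <- make_measurements(ifelse(cens, NA, 0.01), cens,
                         sample_id = sprintf("s%02d", 1:39))
  dr <- detection_rate(m, by = "sample")
  expect_equal(dr, 100 * 20 / 39)
  expect_equal(round(dr), 51)
  # 7 of 8 cells
  oil <- fixture_oil()
  expect_equal(detection_rate(oil[oil$analyte_id == "antioxidant_jx35", ],
                              by = "cell"), 87.5)
  # 0 of 14
  m0 <- make_measurements(rep(NA, 14), rep(TRUE, 14))
  expect_equal(detection_rate(m0, by = "sample"), 0)
})

test_that("composition shares reproduce the survey proportions", {
  eth <- fixture_ethanol_summary()
  tot <- eth[eth$group == "total", ]
  cs <- composition_shares(stats::setNames(tot$mean, tot$analyte_id))
  share <- function(a) cs$share_pct[cs$analyte_id == a]
  expect_equal(round(share("irganox_1010")), 44)
  expect_equal(round(share("irgafos_168")), 39)
  expect_equal(round(share("irganox_1076")), 9)
  expect_equal(round(sum(cs$share_pct[1:3])), 92)
  # conservation before rounding
  expect_equal(sum(cs$share_pct), 100)
  expect_equal(composition_shares(c(only = 3))$share_pct, 100)
  expect_error(composition_shares(c(a = 0, b = 0)), "all.*zero")
})

test_that("SML screening passes at or below the limit, inclusive", {
  reg <- fixture_registry()
  s <- data.frame(analyte_id = c("irganox_1076", "irgafos_168"),
                  max = c(0.4366, 4.2335))
  scr <- sml_screen(s, reg)
  expect_true(all(scr$pass))
  expect_equal(scr$sml[scr$analyte_id == "irganox_1076"], 6)
  expect_equal(scr$margin[scr$analyte_id == "irgafos_168"], 10 - 4.2335)
  # boundary: max exactly at the limit still passes
  at <- sml_screen(data.frame(analyte_id = "irganox_1076", max = 6), reg)
  expect_true(at$pass)
  over <- sml_screen(data.frame(analyte_id = "irganox_1076", max = 6.01),
                     reg)
  expect_false(over$pass)
})

test_that("analyte correlation matrix behaves like Pearson r", {
  x <- c(0.01, 0.02, 0.03, 0.05, 0.08)
  m <- rbind(make_measurements(x, rep(FALSE, 5), analyte_id = "a"),
             make_measurements(2 * x, rep(FALSE, 5), analyte_id = "b"),
             make_measurements(max(x) - x, rep(FALSE, 5),
                               analyte_id = "c"))
  out <- correlate_analytes(as_migration_data(m))
  expect_equal(unname(diag(out$r)), rep(1, 3))
  expect_equal(out$r, t(out$r))
  expect_equal(out$r["a", "b"], 1)
  expect_equal(out$r["a", "c"], -1)
  # hand-computed Pearson r for {1,2,3} vs {1,2,4}
  m2 <- rbind(make_measurements(c(1, 2, 3), rep(FALSE, 3),
                                analyte_id = "a"),
              make_measurements(c(1, 2, 4), rep(FALSE, 3),
                                analyte_id = "b"))
  out2 <- correlate_analytes(as_migration_data(m2))
  expect_equal(out2$r["a", "b"], 3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_equal(round(out2$r["a", "b"], 3), 0.982)
  expect_true(all(out2$p[upper.tri(out2$p)] <= 1))
  # zero variance is flagged, not crashed
  m3 <- rbind(make_measurements(c(1, 1, 1), rep(FALSE, 3),
                                analyte_id = "a"),
              make_measurements(c(1, 2, 4), rep(FALSE, 3),
                                analyte_id = "b"))
  out3 <- correlate_analytes(as_migration_data(m3))
  expect_true(is.na(out3$r["a", "b"]))
  expect_true(out3$flagged["a", "b"])
})
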