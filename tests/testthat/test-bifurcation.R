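test_that("envelope extrema of simple signals collapse correctly", {
  t <- seq(0, 365 * 12, by = 0.5)
  s <- 7 + 2 * sin(2 * pi * t / 365)
  ee <- envelope_extrema(s, t)
  expect_identical(length(planktonchaos:::collapse_values(ee$maxima)), 1L)
  expect_equal(unique(round(ee$maxima, 3)), 9)
  expect_equal(unique(round(ee$minima, 3)), 5)
  # all retained maxima at least 30 days apart
  expect_true(all(diff(sort(ee$t_max)) >= 30))
  cc <- envelope_extrema(rep(3, 8000), seq(0, 7999) * 0.5)
  expect_identical(cc$maxima, 3)
  expect_identical(cc$minima, 3)
})

test_that("a two-period signal yields two distinct maxima per cycle", {
  t <- seq(0, 365 * 12, by = 0.25)
  s <- 10 + 2 * sin(2 * pi * t / 365) + 1 * sin(2 * pi * t / 730)
  ee <- envelope_extrema(s, t)
  vals <- planktonchaos:::collapse_values(ee$maxima, rel_tol = 1e-3)
  expect_identical(length(vals), 2L)
  # brute-force oracle: extrema of the closed form on a fine grid
  tf <- seq(365 * 2, 365 * 12, by = 0.01)
  sf <- 10 + 2 * sin(2 * pi * tf / 365) + 1 * sin(2 * pi * tf / 730)
  peaks <- sf[which(diff(sign(diff(sf))) == -2) + 1]
  expect_equal(sort(vals), sort(unique(round(peaks, 4))), tolerance = 1e-3)
})

test_that("30-day thinning keeps the more extreme of two close peaks", {
  t <- seq(0, 365 * 11, by = 0.5)
  base <- 5 + sin(2 * pi * t / 365)
  bump <- 0.8 * exp(-((t %% 365) - 100)^2 / 18)   # secondary peak 10 d later
  s <- base + 0.5 * exp(-((t %% 365) - 90)^2 / 18) + bump
  ee <- envelope_extrema(s, t)
  # the pair is < 30 d apart: only the larger (bump at day 100) survives
  expect_true(all(abs((ee$t_max %% 365) - 100) < 5))
})

test_that("plateaus are reported once at their midpoint", {
  s <- c(1:10, rep(10, 11), 10:1)
  t <- seq_along(s) * 10
  ee <- envelope_extrema(s, t, min_separation = 30, window_years = NULL)
  expect_identical(ee$maxima, 10)
  expect_identical(length(ee$t_max), 1L)
})

test_that("the unforced ES diagram is a single point per pool", {
  bd <- build_bifurcation(preset_config("ES"), amplitudes = 0,
                          years = 14, window_years = 4,
                          lambda_measure_years = 20)
  counts <- table(bd$points$pool)
  expect_true(all(counts == 2))  # one max + one min, coincident values
  spread <- tapply(bd$points$value, bd$points$pool,
                   function(v) diff(range(v)) / max(v))
  expect_lt(max(spread), 1e-3)
  expect_false(any(bd$points$chaotic))
  expect_s3_class(bd, "bifurcation_diagram")
})

test_that("diagram construction is deterministic and stores lambda per amplitude", {
  b1 <- build_bifurcation(preset_config("EP"), amplitudes = c(0, 2),
                          years = 14, window_years = 4,
                          lambda_measure_years = 20)
  b2 <- build_bifurcation(preset_config("EP"), amplitudes = c(0, 2),
                          years = 14, window_years = 4,
                          lambda_measure_years = 20)
  expect_identical(b1$points, b2$points)
  expect_identical(names(b1$lambda), c("0", "2"))
  f <- tempfile(fileext = ".csv")
  write_bifurcation_csv(b1, f)
  expect_identical(nrow(utils::read.csv(f)), nrow(b1$points))
  unlink(f)
})
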