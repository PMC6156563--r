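test_that("AFI matches the peak-to-later-trough definition on known cases", {
  # no freezing: cumulative curve monotone increasing
  expect_identical(afi(rep(10, 365)), 0)
  # one 10-day cold spell at -5: deficit 50 degree-days
  x <- rep(10, 365); x[150:159] <- -5
  expect_equal(afi(x), 50)
  # interleaved thaw partially refills the deficit: 50 - 6 + 10 = 54
  y <- rep(10, 365)
  y[100:104] <- -10; y[105:107] <- 2; y[108:112] <- -2
  expect_equal(afi(y), 54)
  # cold from the very first day still counts (origin on the curve)
  z <- rep(10, 365); z[1:5] <- -8
  expect_equal(afi(z), 40)
  expect_error(afi(c(rep(1, 100), NA, rep(1, 264))), "missing")
})

test_that("AFI equals the brute-force pairwise maximum on random series", {
  set.seed(101)
  for (r in 1:300) {
    x <- rnorm(60, mean = runif(1, -5, 10), sd = 8)
    expect_equal(afi(x), afiBruteForce(x), tolerance = 1e-12)
  }
})

test_that("tmax10 is the maximum 10-day moving mean", {
  expect_equal(tmax10(rep(20, 365)), 20)
  x <- rep(10, 365); x[100:109] <- 30
  expect_equal(tmax10(x), 30)
  y <- rep(10, 365); y[5] <- 30
  expect_equal(tmax10(y), 12)  # (30 + 9*10)/10
  expect_error(tmax10(rep(1, 9)), "at least 10")
  set.seed(102)
  for (r in 1:200) {
    x <- rnorm(50, 15, 6)
    expect_equal(tmax10(x), tmax10BruteForce(x), tolerance = 1e-12)
  }
})

test_that("winter SWE index is the Dec-Apr mean with range checks", {
  expect_equal(sweWinter(rep(0.5, 5)), 0.5)
  expect_equal(sweWinter(c(0.1, 0.2, 0.3, 0.4, 0.5)), 0.3)
  expect_error(sweWinter(c(0.1, 0.2, 1.2, 0.4, 0.5)), "\\[0, 1\\]")
  expect_error(sweWinter(c(0.1, 0.2, 0.3)), "five")
})

test_that("summer soil moisture averages the Jun 15 - Aug 31 window only", {
  doy <- 1:365
  expect_equal(soilSummer(rep(0.7, 365), doy), 0.7)
  v <- ifelse(doy >= 166 & doy <= 243, 1, 0)
  expect_equal(soilSummer(v, doy), 1)
  half <- ifelse(doy >= 166 & doy <= 204, 0.2, 0.6)[166:243]
  expect_equal(soilSummer(half, 166:243), mean(half))
  expect_error(soilSummer(c(0.5, 0.5), c(10, 20)), "no soil")
})

test_that("baseline standardization gives exact zero-mean unit-SD anomalies", {
  set.seed(103)
  base <- rnorm(30, 100, 15)
  a <- standardizeAnomalies(base)
  expect_lt(abs(mean(a)), 1e-9)
  expect_lt(abs(sd(a) - 1), 1e-9)
  expect_equal(standardizeAnomalies(base, mean(base)), 0)
  expect_equal(standardizeAnomalies(base, mean(base) + sd(base)), 1)
  expect_error(standardizeAnomalies(rep(3, 30)), "masked")
})

test_that("log-logistic PWM fit recovers quantiles and SPEI transforms", {
  set.seed(104)
  # sample from a known log-logistic via inverse CDF
  u <- runif(400)
  x <- 10 + 30 * (u / (1 - u))^(1 / 4)
  fit <- fitLogLogistic(x)
  expect_identical(fit$family, "loglogistic")
  expect_equal(fit$beta, 4, tolerance = 0.5)
  # fitted median maps to SPEI 0; CDF 0.975 maps to 1.96
  med <- fit$gamma + fit$alpha
  expect_lt(abs(qnorm(plotProbability(fit, med))), 1e-9)
  x975 <- fit$gamma + fit$alpha * (1 / 0.975 - 1)^(-1 / fit$beta)
  expect_equal(qnorm(plotProbability(fit, x975)), qnorm(0.975),
               tolerance = 0.005)
  expect_error(fitLogLogistic(rep(5, 40)), "degenerate")
})

test_that("SPEI is standard-normal-ish over calibration years and monotone in D", {
  set.seed(105)
  years <- 1981:2012
  mon <- expand.grid(year = years, month = 1:12)
  mon$tmean_c <- 8 + 12 * cos(2 * pi * (mon$month - 7) / 12) + rnorm(nrow(mon), 0, 1.5)
  mon$precip_mm <- rgamma(nrow(mon), 4, scale = 20)
  sp <- spei3(mon, latitude = 42, end_month = 5, baseline_years = 1982:2012)
  cal <- sp$spei[sp$year %in% 1982:2012]
  expect_lt(abs(mean(cal)), 0.15)
  expect_true(all(diff(sp$spei[order(sp$D)]) >= 0))  # monotone in D
  expect_error(spei3(mon[mon$year > 2000, ], 42, 5), "calibration")
})

test_that("inclusion rules mask by mean AFI and habitat", {
  sites <- c(s1 = 15, s2 = 100, s3 = 250)
  hab <- c(s1 = "wetland", s2 = "stream", s3 = "terrestrial")
  d <- data.frame(site = names(sites), year = 2000L,
                  afi_raw = 1, tmax10_raw = 20, swe_raw = 0.5,
                  spei_raw = 0, soil_raw = 0.5,
                  afi_anom = 0.1, tmax10_anom = 0.1, swe_anom = 0.1,
                  spei_anom = 0.1, soil_anom = 0.1,
                  afi_included = TRUE, swe_included = TRUE,
                  spei_included = TRUE)
  ca <- new("ClimateAnnual", data = d, baselineYears = 1970:1999)
  out <- climateTable(applyInclusion(ca, sites, hab))
  expect_equal(out$afi_included, c(FALSE, TRUE, TRUE))
  expect_equal(out$swe_included, c(FALSE, FALSE, TRUE))
  expect_equal(out$spei_included, c(TRUE, TRUE, FALSE))
  # masked variables are explicit missing, not zeros
  expect_true(is.na(out$afi_raw[1]) && is.na(out$afi_anom[1]))
  expect_true(is.na(out$spei_raw[3]))
  # design assembly converts masked anomalies to structural zeros
  A <- designAnomalies(applyInclusion(ca, sites, hab),
                       out$site, out$year)
  expect_equal(unname(A[1, "afi"]), 0)
  expect_false(attr(A, "included")[1, "afi"])
})

test_that("weather-to-climate pipeline standardizes against its baseline", {
  prof <- data.frame(site = c("cold", "warm"), mean_temp_c = c(2, 18),
                     seasonal_amp_c = c(14, 6), precip_mean_mm = c(2.5, 2),
                     latitude = c(45, 32), noise_sd_c = c(1.5, 1.5))
  w <- simulateWeather(prof, n_years = 33, start_year = 1981, seed = 5)
  sites <- data.frame(site = prof$site, habitat = c("wetland", "wetland"),
                      latitude = prof$latitude, breeding_month = 5L)
  ca <- computeClimateAnnual(w$weather, w$indices, sites,
                             baseline_years = 1982:2011)
  d <- climateTable(ca)
  bl <- d[d$year %in% 1982:2011, ]
  for (s in prof$site) {
    for (v in c("tmax10", "soil")) {
      a <- bl[[paste0(v, "_anom")]][bl$site == s]
      expect_lt(abs(mean(a, na.rm = TRUE)), 1e-9)
      expect_lt(abs(sd(a, na.rm = TRUE) - 1), 1e-9)
    }
  }
  # the cold site freezes (AFI retained); the warm site does not
  expect_true(all(bl$afi_included[bl$site == "cold"]))
  expect_true(all(!bl$afi_included[bl$site == "warm"]))
  expect_true(all(is.na(bl$afi_anom[bl$site == "warm"])))
})

test_that("climate CSV round-trips losslessly including masks", {
  prof <- data.frame(site = "s1", mean_temp_c = 5, seasonal_amp_c = 12,
                     precip_mean_mm = 2.5, latitude = 44)
  w <- simulateWeather(prof, n_years = 32, start_year = 1982, seed = 8)
  sites <- data.frame(site = "s1", habitat = "terrestrial", latitude = 44,
                      breeding_month = 5L)
  ca <- computeClimateAnnual(w$weather, w$indices, sites, 1983:2012)
  f <- withr::local_tempfile(fileext = ".csv")
  writeClimateCSV(ca, f)
  back <- readClimateCSV(f, baseline_years = baselineYears(ca))
  d0 <- climateTable(ca); d1 <- climateTable(back)
  d1 <- d1[, names(d0)]
  expect_equal(d1, d0, tolerance = 1e-12, ignore_attr = TRUE)
})
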