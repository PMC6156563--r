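test_that("degenerate limits force perfect detection of saturated occupancy", {
  # alpha, psi1, p pushed to their limits: every site occupied and every
  # visit a detection
  cfg <- simConfig(n_study_areas = 2, n_species = 2, n_sites_per_area = 5,
                   n_years = 4, n_visits = 2,
                   true_beta = rep(0, 5),
                   mu_alpha = 30, sigma_alpha = 0, mu_delta = 0,
                   sigma_delta = 0, mu_p = 30, sigma_p = 0,
                   mu_psi1 = 30, sigma_psi1 = 0, seed = 1)
  st <- simulateStudy(cfg)
  expect_true(all(observations(st$survey)$detected == 1L))
})

test_that("null configuration yields fair-coin transitions", {
  # beta = 0 and all logit parameters 0: every transition probability 0.5
  cfg <- simConfig(n_study_areas = 1, n_species = 5,
                   n_sites_per_area = 100, n_years = 21, n_visits = 1,
                   true_beta = rep(0, 5),
                   mu_alpha = 0, sigma_alpha = 0, mu_delta = 0,
                   sigma_delta = 0, mu_p = 0, sigma_p = 0,
                   mu_psi1 = 0, sigma_psi1 = 0, seed = 3)
  st <- simulateStudy(cfg)
  z <- surveyTruth(st$survey)$z
  z <- z[order(z$site, z$species, z$year), ]
  zw <- matrix(z$z, ncol = 21, byrow = TRUE)
  trans <- as.vector(zw[, -1])          # states after a transition
  n <- length(trans)                    # 100*5*20 = 1e4 site-years
  expect_gte(n, 1e4)
  mcse <- sqrt(0.25 / n)
  expect_lt(abs(mean(trans) - 0.5), 3 * mcse)
})

test_that("transition frequencies follow the generative recursion", {
  # fixed random effects, nonzero climate effects: empirical conditional
  # frequencies must match plogis(alpha + delta z + beta X)
  cfg <- simConfig(n_study_areas = 1, n_species = 4,
                   n_sites_per_area = 150, n_years = 12, n_visits = 1,
                   true_beta = c(0.5, -0.3, 0, 0, 0),
                   mu_alpha = -0.8, sigma_alpha = 0, mu_delta = 1.6,
                   sigma_delta = 0, mu_p = 0.4, sigma_p = 0,
                   mu_psi1 = 0, sigma_psi1 = 0, seed = 9)
  st <- simulateStudy(cfg)
  z <- surveyTruth(st$survey)$z
  z <- z[order(z$site, z$species, z$year), ]
  Tn <- cfg$n_years
  zw <- matrix(z$z, ncol = Tn, byrow = TRUE)
  key <- unique(z[, c("site", "species")])
  A <- designAnomalies(st$climate, rep(key$site, each = Tn),
                       rep(sort(unique(z$year)), times = nrow(key)))
  eta <- matrix(A %*% cfg$true_beta, ncol = Tn, byrow = TRUE)
  zprev <- as.vector(zw[, -Tn])
  znext <- as.vector(zw[, -1])
  pr <- plogis(cfg$mu_alpha + cfg$mu_delta * zprev +
                 as.vector(eta[, -1]))
  # bin by predicted probability and compare to empirical frequency
  bins <- cut(pr, quantile(pr, seq(0, 1, 0.2)), include.lowest = TRUE)
  for (b in levels(bins)) {
    sel <- bins == b
    se <- sqrt(mean(pr[sel]) * (1 - mean(pr[sel])) / sum(sel))
    expect_lt(abs(mean(znext[sel]) - mean(pr[sel])), 4 * se + 0.005)
  }
})

test_that("detection frequency at occupied site-years matches the logit-normal mean", {
  cfg <- simConfig(n_study_areas = 4, n_species = 8,
                   n_sites_per_area = 40, n_years = 10, n_visits = 2,
                   true_beta = rep(0, 5), mu_p = 0.5, sigma_p = 0.75,
                   seed = 21)
  st <- simulateStudy(cfg)
  obs <- observations(st$survey)
  z <- surveyTruth(st$survey)$z
  zz <- z$z[match(paste(obs$site, obs$species, obs$year),
                  paste(z$site, z$species, z$year))]
  occDet <- obs$detected[zz == 1L]
  set.seed(1)
  oracle <- mean(plogis(rnorm(2e5, cfg$mu_p, cfg$sigma_p)))
  # p varies at (study area, species, year) level: 320 clusters, so the
  # tolerance is ~3 cluster-level standard errors
  expect_lt(abs(mean(occDet) - oracle), 0.025)
})

test_that("the survey generator is deterministic given its seed", {
  cfg <- simConfig(n_study_areas = 2, n_species = 3,
                   n_sites_per_area = 8, n_years = 5, seed = 42)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(observations(s1$survey), observations(s2$survey))
  expect_identical(climateTable(s1$climate), climateTable(s2$climate))
})

test_that("configuration contracts are enforced", {
  expect_error(simConfig(n_years = 2), "n_years")
  expect_error(simConfig(n_species = 0), "counts")
  expect_error(simConfig(true_beta = c(1, 2)), "length 5")
  expect_error(simConfig(sigma_alpha = -1), "sigma")
})

test_that("survey generation fails loudly on missing climate coverage", {
  cfg <- simConfig(n_study_areas = 1, n_species = 2,
                   n_sites_per_area = 4, n_years = 5, seed = 2)
  sites <- simulateSiteTable(1, 4, 2)
  climate <- simulateAnomalies(sites$site, 1:3, 2)  # too few years
  expect_error(simulateSurveys(cfg, climate, sites = sites), "years")
  climate2 <- simulateAnomalies(sites$site[-1], 1:5, 2)  # missing site
  expect_error(simulateSurveys(cfg, climate2, sites = sites),
               "missing")
})

test_that("weather generator honours noise, trend and warmth settings", {
  base <- data.frame(site = "x", mean_temp_c = 3, seasonal_amp_c = 12,
                     precip_mean_mm = 2, latitude = 45)
  # zero noise, zero trend: every year identical, so identical AFI
  p0 <- base; p0$noise_sd_c <- 0
  w0 <- simulateWeather(p0, n_years = 4, start_year = 2000, seed = 1)
  afis <- vapply(2001:2003, function(y) {
    prev <- w0$weather$tmean_c[w0$weather$year == y - 1 &
                                 w0$weather$doy >= 213]
    cur <- w0$weather$tmean_c[w0$weather$year == y & w0$weather$doy < 213]
    afi(c(prev, cur))
  }, numeric(1))
  expect_gt(afis[1], 0)
  expect_lt(max(afis) - min(afis), 1e-9)
  # warm site: daily means above zero, AFI identically 0
  pw <- data.frame(site = "w", mean_temp_c = 20, seasonal_amp_c = 5,
                   precip_mean_mm = 2, latitude = 30, noise_sd_c = 0)
  ww <- simulateWeather(pw, n_years = 3, start_year = 2000, seed = 1)
  expect_true(all(ww$weather$tmean_c > 0))
  # configured warming trend is recovered by OLS on annual means
  pt <- base; pt$noise_sd_c <- 0.5; pt$trend_c_per_year <- 0.02
  wt <- simulateWeather(pt, n_years = 30, start_year = 1985, seed = 4)
  ann <- aggregate(tmean_c ~ year, data = wt$weather, FUN = mean)
  slope <- unname(coef(lm(tmean_c ~ year, ann))[2])
  expect_equal(slope, 0.02, tolerance = 0.35)
  expect_error(simulateWeather(base, n_years = 0), "positive")
  # monthly indices stay inside [0, 1]
  expect_true(all(wt$indices$swe_quantile >= 0 &
                    wt$indices$swe_quantile <= 1))
  expect_true(all(wt$indices$soil_moisture >= 0 &
                    wt$indices$soil_moisture <= 1))
})

test_that("trait generator respects missingness, seed and the no-signal limit", {
  tr0 <- simulateTraitsPhylo(12, missing_fraction = 0, lambda_true = 1,
                             seed = 5)
  expect_false(anyNA(tr0$traits))
  tr1 <- simulateTraitsPhylo(12, missing_fraction = 0.1, seed = 5)
  tr2 <- simulateTraitsPhylo(12, missing_fraction = 0.1, seed = 5)
  expect_identical(tr1$traits, tr2$traits)
  expect_error(simulateTraitsPhylo(12, missing_fraction = 1), "missing_fraction")
  # lambda = 0: trait similarity unrelated to phylogenetic distance
  cors <- vapply(1:200, function(r) {
    g <- simulateTraitsPhylo(10, missing_fraction = 0, lambda_true = 0,
                             seed = 1000 + r)
    D <- phyloDistances(g$tree)
    td <- as.matrix(dist(scale(g$traits[, -1])))
    lo <- lower.tri(D)
    cor(D[lo], td[lo])
  }, numeric(1))
  expect_gt(t.test(cors)$p.value, 0.01)
})

test_that("survey CSV round-trips losslessly", {
  st <- tinyStudy(seed = 13)
  f <- tempfile(fileext = ".csv")
  writeSurveyCSV(st$survey, f)
  back <- readSurveyCSV(f, sites = siteTable(st$survey),
                        species = speciesTable(st$survey))
  expect_equal(observations(back), observations(st$survey),
               ignore_attr = TRUE)
})
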