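## Annual climate drivers: air-freezing index, peak 10-day temperature,
## winter SWE, 3-month SPEI, summer soil moisture; per-site 30-year
## standardization and AFI-based inclusion rules.

# fixed 365-day calendar (no leap days) keeps window arithmetic exact
.MONTH_LEN <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_END <- cumsum(.MONTH_LEN)
.DOY_AUG1 <- 213L   # Aug 1
.DOY_JUN15 <- 166L  # Jun 15
.DOY_AUG31 <- 243L  # Aug 31

#' Day-of-year to month on the fixed 365-day calendar
#' @param doy integer day of year, 1..365.
#' @return Integer month 1..12.
#' @keywords internal
doyToMonth <- function(doy) {
  findInterval(doy - 1L, c(0L, .MONTH_END))
}

#' Air-freezing index (winter severity)
#'
#' Winter severity over an August 1 -- July 31 year, computed from the
#' cumulative sum of daily mean temperatures: the largest drop from any peak
#' of the cumulative curve to a later trough (the fall peak to spring
#' minimum). The curve starts from zero before the first day, so a winter
#' that is cold from the outset still registers its full deficit. A site
#' with no freezing has a monotone increasing curve and an AFI of 0.
#'
#' @param daily_tmean numeric vector of daily mean temperature (degrees C)
#'   covering the full Aug 1 -- Jul 31 window (365 values on the package's
#'   fixed calendar), in day order with no gaps (no `NA`).
#' @return Degree-days (degrees C times days), always >= 0.
#' @export
#' @examples
#' x <- rep(10, 365); x[150:159] <- -5
#' afi(x)  # 50 degree-days
afi <- function(daily_tmean) {
  if (anyNA(daily_tmean)) {
    stop("gap in the Aug 1 - Jul 31 window: missing days at positions ",
         paste(head(which(is.na(daily_tmean)), 10L), collapse = ", "))
  }
  cum <- c(0, cumsum(daily_tmean))
  max(cummax(cum) - cum)
}

#' Highest 10-day moving-average temperature
#'
#' Proxy for realized heat stress: the maximum over all contiguous 10-day
#' windows of the window-mean daily temperature within one calendar year.
#'
#' @param daily_tmean numeric vector of daily mean temperatures (degrees C),
#'   at least 10 values, no `NA`.
#' @return Degrees C.
#' @export
#' @examples
#' tmax10(rep(20, 365))  # 20
tmax10 <- function(daily_tmean) {
  n <- length(daily_tmean)
  if (anyNA(daily_tmean)) stop("daily_tmean contains missing values")
  if (n < 10L) stop("need at least 10 days of data, got ", n)
  cum <- c(0, cumsum(daily_tmean))
  max(cum[11:(n + 1L)] - cum[1:(n - 9L)]) / 10
}

#' Winter snow-water-equivalent index
#'
#' Mean of the monthly SWE quantiles over the winter months December through
#' April (five values; December belongs to the previous calendar year).
#'
#' @param monthly_quantiles numeric vector of the five Dec--Apr monthly SWE
#'   quantiles, each in \[0, 1\].
#' @return Mean winter quantile in \[0, 1\].
#' @export
sweWinter <- function(monthly_quantiles) {
  if (length(monthly_quantiles) != 5L || anyNA(monthly_quantiles))
    stop("need all five Dec-Apr monthly quantiles")
  if (any(monthly_quantiles < 0 | monthly_quantiles > 1))
    stop("SWE quantiles must lie in [0, 1]; got ",
         paste(round(monthly_quantiles[monthly_quantiles < 0 |
                                       monthly_quantiles > 1], 3),
               collapse = ", "))
  mean(monthly_quantiles)
}

#' Summer soil-moisture index
#'
#' Mean soil moisture over June 15 -- August 31 (inclusive).
#'
#' @param values numeric soil-moisture values.
#' @param doy integer day-of-year stamp for each value (fixed 365-day
#'   calendar; Jun 15 = 166, Aug 31 = 243).
#' @return Mean over the window.
#' @export
soilSummer <- function(values, doy) {
  keep <- doy >= .DOY_JUN15 & doy <= .DOY_AUG31
  if (!any(keep)) stop("no soil-moisture values inside Jun 15 - Aug 31")
  mean(values[keep])
}

#' Thornthwaite potential evapotranspiration
#'
#' Monthly PET (mm) from monthly mean temperature and latitude, using the
#' Thornthwaite formulation with the standard day-length correction. The
#' annual heat index is computed from the 12 monthly temperatures of each
#' year.
#'
#' @param tmean_monthly matrix (years x 12) of monthly mean temperature
#'   (degrees C).
#' @param latitude site latitude in decimal degrees.
#' @return Matrix (years x 12) of PET in mm/month.
#' @export
thornthwaitePET <- function(tmean_monthly, latitude) {
  tm <- as.matrix(tmean_monthly)
  if (ncol(tm) != 12L) stop("tmean_monthly must have 12 columns")
  tpos <- pmax(tm, 0)
  I <- rowSums((tpos / 5)^1.514)
  I <- pmax(I, 1e-6)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  # mean day length per month at this latitude (hours)
  midDoy <- .MONTH_END - .MONTH_LEN / 2
  decl <- 0.4093 * sin(2 * pi * midDoy / 365 - 1.405)
  latr <- latitude * pi / 180
  cosw <- pmin(pmax(-tan(latr) * tan(decl), -1), 1)
  N <- 24 * acos(cosw) / pi
  K <- matrix(N / 12, nrow(tm), 12, byrow = TRUE) *
    matrix(.MONTH_LEN / 30, nrow(tm), 12, byrow = TRUE)
  pet <- 16 * K * (10 * tpos / matrix(I, nrow(tm), 12))^
    matrix(a, nrow(tm), 12)
  pet[tpos <= 0] <- 0
  pet
}

#' Fit a three-parameter log-logistic distribution
#'
#' Probability-weighted-moment (unbiased PWM) fit, the standard practice for
#' SPEI calibration. Returns shape `beta`, scale `alpha` and origin `gamma`
#' of \eqn{F(x) = [1 + (\alpha/(x-\gamma))^\beta]^{-1}}. If the PWM solution
#' is invalid (shape <= 1, non-positive scale, or data at or below the fitted
#' origin) the fit falls back to a Gaussian (`family = "normal"`), whose CDF
#' is used in the same way downstream.
#'
#' @param x numeric sample (e.g. 30 baseline water-balance values).
#' @return List with `family` ("loglogistic" or "normal") and parameters;
#'   use [plotProbability()] to evaluate the fitted CDF.
#' @export
fitLogLogistic <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 4L) stop("need at least 4 values to fit")
  if (sd(x) < 1e-12) stop("degenerate (zero-variance) history")
  j <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((j - 1) / (n - 1) * x) / n
  b2 <- sum((j - 1) * (j - 2) / ((n - 1) * (n - 2)) * x) / n
  # PWM relations for b_s = E[X F(X)^s]:
  #   2b1 - b0 = alpha*g1/beta,  b0 + 6b2 - 6b1 = alpha*g1/beta^2,
  #   b0 = gamma + alpha*g1,  with g1 = Gamma(1+1/beta)*Gamma(1-1/beta)
  beta <- (2 * b1 - b0) / (b0 + 6 * b2 - 6 * b1)
  fit <- NULL
  if (is.finite(beta) && beta > 1) {
    g1 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
    alpha <- (2 * b1 - b0) * beta / g1
    gamma0 <- b0 - alpha * g1
    if (is.finite(alpha) && alpha > 0 && all(x > gamma0)) {
      fit <- list(family = "loglogistic", beta = beta, alpha = alpha,
                  gamma = gamma0)
    }
  }
  if (is.null(fit)) {
    fit <- list(family = "normal", mean = mean(x), sd = sd(x))
  }
  fit
}

#' Evaluate the CDF of a fitted water-balance distribution
#'
#' @param fit result of [fitLogLogistic()].
#' @param x numeric values at which to evaluate.
#' @return CDF values clamped to (1e-6, 1 - 1e-6) so the standard-normal
#'   transform stays finite.
#' @export
plotProbability <- function(fit, x) {
  p <- if (fit$family == "loglogistic") {
    z <- pmax(x - fit$gamma, .Machine$double.eps)
    1 / (1 + (fit$alpha / z)^fit$beta)
  } else {
    pnorm(x, fit$mean, fit$sd)
  }
  pmin(pmax(p, 1e-6), 1 - 1e-6)
}

#' 3-month standardized precipitation-evapotranspiration index
#'
#' Water balance D = precipitation - Thornthwaite PET summed over the
#' 3-month window ending at `end_month` (the month of peak breeding
#' activity), fitted across the calibration years to a three-parameter
#' log-logistic distribution by probability-weighted moments; the returned
#' index is the standard-normal quantile of the fitted CDF at each target
#' year's D.
#'
#' @param monthly data.frame with columns `year`, `month`, `precip_mm`,
#'   `tmean_c` covering at least the calibration years (complete 12-month
#'   years; the window may reach into the preceding calendar year).
#' @param latitude site latitude, decimal degrees.
#' @param end_month integer 1..12, final month of the 3-month window.
#' @param target_years years to index (default: all years with a complete
#'   window).
#' @param baseline_years years used to calibrate the distribution (default:
#'   all available); at least 30 required.
#' @return data.frame with columns `year`, `D` (mm) and `spei`.
#' @export
spei3 <- function(monthly, latitude, end_month,
                  target_years = NULL, baseline_years = NULL) {
  need <- c("year", "month", "precip_mm", "tmean_c")
  if (!all(need %in% names(monthly)))
    stop("monthly must have columns: ", paste(need, collapse = ", "))
  years <- sort(unique(monthly$year))
  tm <- matrix(NA_real_, length(years), 12)
  pr <- matrix(NA_real_, length(years), 12)
  iy <- match(monthly$year, years)
  tm[cbind(iy, monthly$month)] <- monthly$tmean_c
  pr[cbind(iy, monthly$month)] <- monthly$precip_mm
  pet <- tm
  ok <- !apply(is.na(tm), 1, any)
  pet[ok, ] <- thornthwaitePET(tm[ok, , drop = FALSE], latitude)
  bal <- pr - pet
  # window D per labeled year: months end_month-2 .. end_month, shifting
  # into the previous year where needed
  windowD <- function(y) {
    mos <- end_month - (2:0)
    yrs <- rep(y, 3L)
    yrs[mos < 1] <- y - 1L
    mos[mos < 1] <- mos[mos < 1] + 12L
    ii <- match(yrs, years)
    if (anyNA(ii)) return(NA_real_)
    v <- bal[cbind(ii, mos)]
    if (anyNA(v)) NA_real_ else sum(v)
  }
  D <- vapply(years, windowD, numeric(1))
  names(D) <- years
  if (is.null(baseline_years)) baseline_years <- years[!is.na(D)]
  Dcal <- D[as.character(baseline_years)]
  if (anyNA(Dcal) || length(Dcal) < 30L)
    stop("insufficient calibration years with a complete 3-month window: ",
         sum(!is.na(Dcal)), " available, 30 required")
  if (sd(Dcal) < 1e-12)
    stop("degenerate (zero-variance) water-balance history")
  fit <- fitLogLogistic(Dcal)
  if (is.null(target_years)) target_years <- years[!is.na(D)]
  Dt <- D[as.character(target_years)]
  data.frame(year = as.integer(target_years), D = unname(Dt),
             spei = qnorm(plotProbability(fit, unname(Dt))))
}

#' Standardize to a site's 30-year baseline
#'
#' Anomalies (x - baseline mean) / baseline SD, with the unbiased (n-1) SD.
#'
#' @param baseline numeric baseline (normal-period) raw values.
#' @param target numeric raw values to standardize (default: the baseline
#'   itself).
#' @return Numeric anomalies in per-baseline-SD units.
#' @export
standardizeAnomalies <- function(baseline, target = baseline) {
  baseline <- baseline[!is.na(baseline)]
  if (length(baseline) < 2L) stop("need at least 2 baseline values")
  s <- sd(baseline)
  if (!is.finite(s) || s < 1e-12)
    stop("constant baseline: zero SD, variable must be masked for this site")
  (target - mean(baseline)) / s
}

#' Apply the AFI-based inclusion rules
#'
#' Winter severity is only modeled where freezing regularly occurs (mean
#' baseline AFI > 20 degree-days); the snow index only where extended snow
#' accumulation is possible (mean baseline AFI > 200); breeding water
#' availability (SPEI) never at terrestrial sites. Masked variables have
#' their raw and anomaly entries set to `NA` (explicit missing, never
#' silent zeros).
#'
#' @param climate a [ClimateAnnual-class] object.
#' @param site_afi_mean named numeric: mean baseline-period AFI per site.
#' @param habitat named character: habitat class per site
#'   (wetland/stream/terrestrial).
#' @return The masked [ClimateAnnual-class] object.
#' @export
applyInclusion <- function(climate, site_afi_mean, habitat) {
  d <- climateTable(climate)
  afiM <- site_afi_mean[as.character(d$site)]
  hab <- habitat[as.character(d$site)]
  if (anyNA(afiM)) stop("mean baseline AFI missing for sites: ",
                        paste(unique(d$site[is.na(afiM)]), collapse = ", "))
  d$afi_included <- unname(afiM > 20)
  d$swe_included <- unname(afiM > 200)
  d$spei_included <- unname(!is.na(hab) & hab != "terrestrial")
  for (v in c("afi", "swe", "spei")) {
    off <- !d[[paste0(v, "_included")]]
    d[[paste0(v, "_raw")]][off] <- NA_real_
    d[[paste0(v, "_anom")]][off] <- NA_real_
  }
  new("ClimateAnnual", data = d, baselineYears = baselineYears(climate))
}

#' Compute annual climate anomalies from weather series
#'
#' Full pipeline from daily weather and monthly snow/soil indices to a
#' [ClimateAnnual-class] object: per (site, year) the air-freezing index
#' (Aug 1 -- Jul 31, labeled by the ending year), the highest 10-day mean
#' temperature, the Dec--Apr SWE quantile mean, 3-month SPEI ending at the
#' site's peak-breeding month, and mean Jun 15 -- Aug 31 soil moisture; each
#' standardized to the site's baseline-window mean and SD, then masked by
#' the AFI inclusion rules.
#'
#' @param weather data.frame: `site`, `year`, `doy` (1..365, fixed
#'   calendar), `tmean_c`, `precip_mm`.
#' @param indices data.frame: `site`, `year`, `month`, `swe_quantile`,
#'   `soil_moisture`.
#' @param sites data.frame: `site`, `habitat`, `latitude`, `breeding_month`
#'   (end month of the 3-month SPEI window).
#' @param baseline_years integer vector, the 30-year normal period.
#' @param target_years years to report (default: baseline and later years
#'   with complete windows).
#' @return A [ClimateAnnual-class] object.
#' @export
computeClimateAnnual <- function(weather, indices, sites, baseline_years,
                                 target_years = NULL) {
  baseline_years <- as.integer(baseline_years)
  out <- list()
  afiMeans <- numeric(0)
  habitats <- character(0)
  for (si in seq_len(nrow(sites))) {
    sid <- sites$site[si]
    w <- weather[weather$site == sid, ]
    ix <- indices[indices$site == sid, ]
    w <- w[order(w$year, w$doy), ]
    yrs <- sort(unique(w$year))
    # AFI labeled by ending (Jul 31) year
    afiv <- setNames(rep(NA_real_, length(yrs)), yrs)
    tmaxv <- afiv; swev <- afiv; soilv <- afiv
    for (y in yrs) {
      prev <- w[w$year == y - 1L & w$doy >= .DOY_AUG1, "tmean_c"]
      cur <- w[w$year == y & w$doy < .DOY_AUG1, "tmean_c"]
      if (length(prev) == 365L - .DOY_AUG1 + 1L &&
          length(cur) == .DOY_AUG1 - 1L)
        afiv[as.character(y)] <- afi(c(prev, cur))
      ty <- w[w$year == y, ]
      if (nrow(ty) == 365L)
        tmaxv[as.character(y)] <- tmax10(ty$tmean_c)
      dec <- ix[ix$year == y - 1L & ix$month == 12L, "swe_quantile"]
      jfma <- ix[ix$year == y & ix$month %in% 1:4, ]
      jfma <- jfma[order(jfma$month), "swe_quantile"]
      if (length(dec) == 1L && length(jfma) == 4L)
        swev[as.character(y)] <- sweWinter(c(dec, jfma))
      dsoil <- ix[ix$year == y & ix$month %in% 6:8, ]
      if (nrow(dsoil) == 3L) {
        # monthly soil values: weight by days inside the Jun 15-Aug 31 window
        wts <- c(16, 31, 31)
        soilv[as.character(y)] <- sum(dsoil$soil_moisture[order(dsoil$month)] *
                                        wts) / sum(wts)
      }
    }
    # SPEI from monthly aggregates of the daily series
    mon <- aggregate(cbind(precip_mm = w$precip_mm, tmean_c = w$tmean_c),
                     by = list(year = w$year, month = doyToMonth(w$doy)),
                     FUN = sum)
    nday <- .MONTH_LEN[mon$month]
    mon$tmean_c <- mon$tmean_c / nday
    sp <- tryCatch(
      spei3(mon, latitude = sites$latitude[si],
            end_month = sites$breeding_month[si],
            baseline_years = baseline_years),
      error = function(e) NULL)
    speiv <- setNames(rep(NA_real_, length(yrs)), yrs)
    if (!is.null(sp)) speiv[as.character(sp$year)] <- sp$spei
    bl <- as.character(baseline_years)
    std <- function(v) {
      if (all(is.na(v[bl])) || sd(v[bl], na.rm = TRUE) < 1e-12)
        return(setNames(rep(NA_real_, length(v)), names(v)))
      a <- v
      a[] <- NA_real_
      okb <- !is.na(v[bl])
      a[!is.na(v)] <- standardizeAnomalies(v[bl][okb], v[!is.na(v)])
      a
    }
    yrsOut <- if (is.null(target_years)) yrs else intersect(yrs, target_years)
    ky <- as.character(yrsOut)
    out[[length(out) + 1L]] <- data.frame(
      site = sid, year = as.integer(yrsOut),
      afi_raw = unname(afiv[ky]), tmax10_raw = unname(tmaxv[ky]),
      swe_raw = unname(swev[ky]), spei_raw = unname(speiv[ky]),
      soil_raw = unname(soilv[ky]),
      afi_anom = unname(std(afiv)[ky]), tmax10_anom = unname(std(tmaxv)[ky]),
      swe_anom = unname(std(swev)[ky]), spei_anom = unname(std(speiv)[ky]),
      soil_anom = unname(std(soilv)[ky]),
      afi_included = TRUE, swe_included = TRUE, spei_included = TRUE)
    afiMeans[as.character(sid)] <- mean(afiv[bl], na.rm = TRUE)
    habitats[as.character(sid)] <- as.character(sites$habitat[si])
  }
  ca <- new("ClimateAnnual", data = do.call(rbind, out),
            baselineYears = baseline_years)
  applyInclusion(ca, afiMeans, habitats)
}

#' Anomaly matrix for design assembly
#'
#' Extracts the five climate anomalies for given (site, year) keys as a
#' matrix, converting masked (`NA`) anomalies to structural zeros: a masked
#' site-year then contributes no information to the masked coefficient.
#'
#' @param climate a [ClimateAnnual-class] object.
#' @param site,year vectors of equal length keying the rows wanted.
#' @return Numeric matrix (length(site) x 5) with columns
#'   [climateVariables()]; attribute `"included"` holds the logical mask
#'   matrix.
#' @export
designAnomalies <- function(climate, site, year) {
  d <- climateTable(climate)
  ii <- match(paste(site, year), paste(d$site, d$year))
  if (anyNA(ii))
    stop("climate rows missing for site-years: ",
         paste(unique(paste(site, year)[is.na(ii)])[1:min(5, sum(is.na(ii)))],
               collapse = "; "))
  A <- cbind(afi = d$afi_anom[ii], tmax10 = d$tmax10_anom[ii],
             swe = d$swe_anom[ii], spei = d$spei_anom[ii],
             soil = d$soil_anom[ii])
  M <- cbind(afi = d$afi_included[ii], tmax10 = TRUE,
             swe = d$swe_included[ii], spei = d$spei_included[ii],
             soil = TRUE)
  M <- M & !is.na(A)
  A[!M] <- 0
  attr(A, "included") <- M
  A
}
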