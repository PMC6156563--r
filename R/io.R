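## Plain-text interchange: survey, climate, weather, trait and scenario CSVs.

#' Write / read detection records as CSV
#'
#' The survey CSV has exactly the columns `study_area`, `site`, `species`,
#' `year`, `visit`, `detected` (0/1) and round-trips losslessly.
#'
#' @param x a [SurveyData-class] object.
#' @param file path to write to / read from.
#' @return `writeSurveyCSV()` returns `file` invisibly; `readSurveyCSV()`
#'   returns a [SurveyData-class] object.
#' @export
writeSurveyCSV <- function(x, file) {
  write.csv(observations(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeSurveyCSV
#' @param sites,species optional metadata tables to attach; when absent a
#'   minimal site table (habitat and ecoregion unknown) is inferred from
#'   the records.
#' @export
readSurveyCSV <- function(file, sites = NULL, species = NULL) {
  obs <- read.csv(file, stringsAsFactors = FALSE)
  obs$detected <- as.integer(obs$detected)
  obs$year <- as.integer(obs$year)
  obs$visit <- as.integer(obs$visit)
  if (is.null(sites)) {
    sites <- unique(obs[, c("site", "study_area")])
    sites$habitat <- NA_character_
    sites$ecoregion <- NA_character_
    sites$norm_temp_c <- NA_real_
    sites$norm_precip_mm <- NA_real_
    rownames(sites) <- NULL
  }
  if (is.null(species))
    species <- data.frame(species = sort(unique(obs$species)),
                          taxon = NA_character_)
  new("SurveyData", observations = obs, sites = sites, species = species,
      truth = list())
}

#' Write / read annual climate anomalies as CSV
#'
#' Long format: `site`, `year`, `var`, `raw`, `anomaly`, `included`, one
#' row per site-year-variable; masked variables have empty raw/anomaly
#' cells and `included = FALSE`.
#'
#' @param x a [ClimateAnnual-class] object.
#' @param file path.
#' @return `writeClimateCSV()` returns `file` invisibly; `readClimateCSV()`
#'   returns a [ClimateAnnual-class].
#' @export
writeClimateCSV <- function(x, file) {
  d <- climateTable(x)
  long <- do.call(rbind, lapply(climateVariables(), function(v) {
    inc <- switch(v, afi = d$afi_included, swe = d$swe_included,
                  spei = d$spei_included, TRUE)
    data.frame(site = d$site, year = d$year, var = v,
               raw = d[[paste0(v, "_raw")]],
               anomaly = d[[paste0(v, "_anom")]],
               included = rep(inc, length.out = nrow(d)))
  }))
  long <- long[order(long$site, long$year, long$var), ]
  write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeClimateCSV
#' @param baseline_years integer vector recorded on the object.
#' @export
readClimateCSV <- function(file, baseline_years = integer()) {
  long <- read.csv(file, stringsAsFactors = FALSE)
  key <- unique(long[, c("site", "year")])
  wide <- key
  for (v in climateVariables()) {
    sub <- long[long$var == v, ]
    ii <- match(paste(key$site, key$year), paste(sub$site, sub$year))
    wide[[paste0(v, "_raw")]] <- sub$raw[ii]
    wide[[paste0(v, "_anom")]] <- sub$anomaly[ii]
    if (v %in% c("afi", "swe", "spei"))
      wide[[paste0(v, "_included")]] <- sub$included[ii]
  }
  rownames(wide) <- NULL
  new("ClimateAnnual", data = wide,
      baselineYears = as.integer(baseline_years))
}

#' Write a scenario report as CSV (and read it back)
#'
#' @param x a [ScenarioResult-class] object.
#' @param file path.
#' @return `writeScenarioCSV()` returns `file` invisibly;
#'   `readScenarioCSV()` returns the report data.frame.
#' @export
writeScenarioCSV <- function(x, file) {
  write.csv(scenarioTable(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeScenarioCSV
#' @export
readScenarioCSV <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}
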