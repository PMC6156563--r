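#' @rdname occusens-accessors
setMethod("observations", "SurveyData", function(x) x@observations)
#' @rdname occusens-accessors
setMethod("siteTable", "SurveyData", function(x) x@sites)
#' @rdname occusens-accessors
setMethod("speciesTable", "SurveyData", function(x) x@species)
#' @rdname occusens-accessors
setMethod("surveyTruth", "SurveyData", function(x) x@truth)

#' @rdname occusens-accessors
setMethod("climateTable", "ClimateAnnual", function(x) x@data)
#' @rdname occusens-accessors
setMethod("baselineYears", "ClimateAnnual", function(x) x@baselineYears)

#' @rdname occusens-accessors
setMethod("designMatrix", "OccupancyDesign", function(x) x@X)
#' @rdname occusens-accessors
setMethod("designKey", "OccupancyDesign", function(x) x@key)
#' @rdname occusens-accessors
setMethod("designTerms", "OccupancyDesign", function(x) x@terms)

#' @rdname occusens-accessors
setMethod("posteriorDraws", "OccupancyFit", function(x) x@draws)
#' @rdname occusens-accessors
setMethod("posteriorSummary", "OccupancyFit", function(x) x@summary)
#' @rdname occusens-accessors
setMethod("isConverged", "OccupancyFit", function(x) x@converged)

#' @rdname occusens-accessors
setMethod("sensitivityTable", "SensitivityResult", function(x) x@table)
#' @rdname occusens-accessors
setMethod("scenarioTable", "ScenarioResult", function(x) x@table)

setMethod("show", "SurveyData", function(object) {
  obs <- object@observations
  cat("SurveyData:", nrow(obs), "visit records |",
      length(unique(obs$study_area)), "study areas,",
      length(unique(obs$site)), "sites,",
      length(unique(obs$species)), "species, years",
      paste(range(obs$year), collapse = "-"), "\n")
  cat("  naive detection frequency:",
      round(mean(obs$detected), 3), "\n")
  if (length(object@truth))
    cat("  simulated data: generating truth attached\n")
})

setMethod("show", "ClimateAnnual", function(object) {
  d <- object@data
  cat("ClimateAnnual:", length(unique(d$site)), "sites x years",
      paste(range(d$year), collapse = "-"),
      "| baseline", paste(range(object@baselineYears), collapse = "-"), "\n")
  cat("  included: afi", sum(d$afi_included), "/", nrow(d),
      " swe", sum(d$swe_included), "/", nrow(d),
      " spei", sum(d$spei_included), "/", nrow(d), "\n")
})

setMethod("show", "OccupancyDesign", function(object) {
  cat("OccupancyDesign:", nrow(object@X), "transition rows x",
      ncol(object@X), "columns (",
      sum(object@terms$type == "main"), "mains,",
      sum(object@terms$type == "interaction"), "interactions )\n")
})

setMethod("show", "OccupancyFit", function(object) {
  ctl <- object@control
  cat("OccupancyFit:", length(object@draws), "chains x",
      nrow(object@draws[[1]]), "kept draws of",
      ncol(object@draws[[1]]), "parameters\n")
  cat("  iterations:", ctl$n_iter, "after", ctl$n_burn,
      "burn-in, thin", ctl$thin, "\n")
  cat("  max split R-hat:", round(max(object@rhat), 4),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
})

setMethod("show", "SensitivityResult", function(object) {
  tab <- object@table
  cat("SensitivityResult:", nrow(tab), "(species x study area x variable)",
      "rows;", sum(tab$included), "included\n")
})

setMethod("show", "ScenarioResult", function(object) {
  tab <- object@table
  cat("ScenarioResult:", length(unique(tab$scenario_id)), "scenarios,",
      "modes:", paste(unique(tab$mode), collapse = ", "), "\n")
})
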