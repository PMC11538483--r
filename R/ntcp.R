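#' Logistic NTCP model parameters
#'
#' Normal tissue complication probability is modelled as a logistic
#' transform of a linear predictor driven by an organ's mean dose plus
#' optional clinical covariates:
#' `NTCP = 1 / (1 + exp(-(intercept + slope * dose + sum(coef * cov))))`.
#'
#' @param endpoint endpoint name (e.g. `"mortality_2yr"`).
#' @param metric driving dose metric name (e.g. `"MHD"`).
#' @param intercept model intercept.
#' @param slope_per_gy per-Gy coefficient of the mean dose.
#' @param covariates named list of covariate coefficients (may be
#'   empty); every named covariate must be supplied when evaluating.
#' @return an `ntcp_model`.
#' @export
ntcp_model <- function(endpoint, metric, intercept, slope_per_gy,
                       covariates = list()) {
  structure(list(endpoint = endpoint, metric = metric,
                 intercept = intercept, slope_per_gy = slope_per_gy,
                 covariates = covariates), class = "ntcp_model")
}

#' Default NTCP model set for lung proton therapy endpoints
#'
#' Three mean-dose-driven logistic models: 2-year mortality (mean heart
#' dose), grade >= 2 radiation pneumonitis (mean lung dose) and grade >=
#' 2 dysphagia (mean esophageal dose).  The coefficients shipped here
#' are editable literature-informed surrogates for a national indication
#' protocol whose exact parameters are not redistributed with this
#' package; replace them with protocol values for any clinical-style
#' analysis.
#'
#' @return named list of [ntcp_model()] objects.
#' @export
default_ntcp_models <- function() {
  list(
    mortality_2yr = ntcp_model("mortality_2yr", "MHD",
                               intercept = -1.49, slope_per_gy = 0.063),
    pneumonitis_g2 = ntcp_model("pneumonitis_g2", "MLD",
                                intercept = -3.87, slope_per_gy = 0.126),
    dysphagia_g2 = ntcp_model("dysphagia_g2", "MED",
                              intercept = -4.43, slope_per_gy = 0.097)
  )
}

#' Evaluate an NTCP model
#'
#' @param model an [ntcp_model()].
#' @param mean_dose_gy the driving mean organ dose (Gy).
#' @param covariates named list of covariate values; all covariates
#'   named in the model must be present.
#' @return complication probability in (0, 1).
#' @export
ntcp <- function(model, mean_dose_gy, covariates = list()) {
  s <- model$intercept + model$slope_per_gy * mean_dose_gy
  for (nm in names(model$covariates)) {
    if (is.null(covariates[[nm]]))
      stop("missing required covariate: ", nm)
    s <- s + model$covariates[[nm]] * covariates[[nm]]
  }
  stats::plogis(s)
}
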