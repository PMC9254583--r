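#' Packaged study data: experiment table, published weights, frozen scaler
#'
#' `study_table()` returns the 28-treatment pistachio seed disinfection
#' experiment (a sterile-water control plus 27 chemical treatments of NaOCl,
#' H2O2 and HgCl2 at three levels and three immersion times), including the
#' published model predictions and residuals. The control has no NDE
#' observation: every control culture was contaminated, and NDE is scored on
#' contamination-free cultures only.
#'
#' `published_mlp()` returns the published 4-10-2 network parameters and
#' `published_scaler()` the frozen min-max ranges under which those parameters
#' reproduce the published predicted columns (inputs scaled over the full
#' 28-record table, responses over \[0, 100\], target range \[-1, 1\]).
#'
#' @return see above.
#' @export
study_table <- function() {
  load_table(system.file("extdata", "study_treatments.csv",
                         package = "disinfopt", mustWork = TRUE),
             provenance = "published 28-treatment study table")
}

#' @rdname study_table
#' @export
published_mlp <- function() {
  read_mlp_params(system.file("extdata", "published_weights.txt",
                              package = "disinfopt", mustWork = TRUE))
}

#' @rdname study_table
#' @export
published_scaler <- function() {
  read_scaler(system.file("extdata", "published_scaler.txt",
                          package = "disinfopt", mustWork = TRUE))
}

#' Published model-validation metrics and optimum
#'
#' Reference values reported for the study: the model's RMSE and R-squared
#' per output, the training/validation/testing/all correlation coefficients,
#' and the protocol recommended by the multi-objective optimization
#' (NaOCl \%, H2O2 \%, HgCl2 \%, immersion minutes).
#'
#' @return a list with elements `rmse`, `r2`, `r` and `optimum`.
#' @export
published_metrics <- function() {
  list(
    rmse = c(de = 11.088993, nde = 13.5210135),
    r2 = c(de = 0.80406535, nde = 0.83894514),
    r = c(train = 0.9658, validation = 0.9653, test = 0.8937, all = 0.9454),
    optimum = c(naocl = 0.563, h2o2 = 12.232, hgcl2 = 0.068, time = 5.022)
  )
}
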