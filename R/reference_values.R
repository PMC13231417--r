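#' Published human exposure observations and predictions
#'
#' The printed observed and predicted dose-normalized human exposures
#' (DCmax in 1/mL, DAUC(0-inf) in h/mL) of the three mRNA-LNP-encoded
#' antibodies - RiboMab01 (BNT141), RiboMab02.1 (BNT142) and CHKV-24
#' (mRNA-1944) - under both prediction methods: generalized-exponent
#' allometric scaling (mouse exponent -1.26, NHP exponent -0.75) and
#' single-species projection of the mechanistic translational model.
#' mRNA-1944 has NHP-based predictions only. These serve as worked-example
#' inputs for the fold-error report layer; fold errors are always
#' recomputed from these values rather than copied, since two printed
#' fold entries for mRNA-1944 are inconsistent with their own inputs
#' (apparently swapped or rounded upstream).
#'
#' @return data.frame with columns `compound`, `parameter`, `method`,
#'   `source_species`, `observed`, `predicted`.
#' @export
#' @examples
#' rep <- prediction_report(reference_exposure_predictions())
#' summary(rep)
reference_exposure_predictions <- function() {
  rbind(
    # allometric scaling predictions
    data.frame(compound = "BNT141", parameter = "DCmax",
               method = "allometry",
               source_species = c("mouse", "nhp"),
               observed = 6.96e-4, predicted = c(5.72e-4, 1.15e-3)),
    data.frame(compound = "BNT141", parameter = "DAUC",
               method = "allometry",
               source_species = c("mouse", "nhp"),
               observed = 0.28, predicted = c(0.063, 0.18)),
    data.frame(compound = "BNT142", parameter = "DCmax",
               method = "allometry",
               source_species = c("mouse", "nhp"),
               observed = 1.93e-5, predicted = c(5.70e-5, 2.23e-5)),
    data.frame(compound = "BNT142", parameter = "DAUC",
               method = "allometry",
               source_species = c("mouse", "nhp"),
               observed = 1.29e-3, predicted = c(2.6e-3, 1.10e-3)),
    data.frame(compound = "mRNA-1944", parameter = c("DCmax", "DAUC"),
               method = "allometry", source_species = "nhp",
               observed = c(3.02e-4, 0.42),
               predicted = c(5.23e-4, 0.19)),
    # translational-model predictions
    data.frame(compound = "BNT141", parameter = "DAUC",
               method = "model", source_species = c("mouse", "nhp"),
               observed = 0.28, predicted = c(0.078, 0.33)),
    data.frame(compound = "BNT141", parameter = "DCmax",
               method = "model", source_species = c("mouse", "nhp"),
               observed = 6.96e-4, predicted = c(2.13e-4, 8.00e-4)),
    data.frame(compound = "BNT142", parameter = "DAUC",
               method = "model", source_species = c("mouse", "nhp"),
               observed = 0.0013, predicted = c(0.0035, 0.0012)),
    data.frame(compound = "BNT142", parameter = "DCmax",
               method = "model", source_species = c("mouse", "nhp"),
               observed = 1.93e-5, predicted = c(3.63e-5, 1.45e-5)),
    data.frame(compound = "mRNA-1944", parameter = c("DCmax", "DAUC"),
               method = "model", source_species = "nhp",
               observed = c(3.02e-4, 0.42),
               predicted = c(2.23e-4, 0.28))
  )
}
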