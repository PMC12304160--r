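#' Packaged reference table of observed and predicted parameters
#'
#' Read-only fixture of the published example table: for 9 direct lengths
#' and 7 surface curves, the observed (n = 25) and predicted (n = 202)
#' mean, median and SD in mm, with each row mapped to its registry
#' parameter id. (Two obvious typographical slips in the printed medians
#' are normalized: "20.1.1" to 20.1 and "18.1." to 18.1.)
#'
#' @return Data.frame with 16 rows and columns no, parameter, kind,
#'   param_id, observed_mean, observed_median, observed_sd, predicted_mean,
#'   predicted_median, predicted_sd.
#' @export
load_reference_table <- function() {
  path <- system.file("extdata", "table3_reference.csv", package = "naso3d",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 16L)
  tab
}
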