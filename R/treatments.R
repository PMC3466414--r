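#' Reference linker-amplification treatment design
#'
#' The treatment metadata of a reference assessment study bundled with the
#' package: a clonal phage isolate amplified at 15-30 PCR cycles from
#' 10 ng down to 1 pg input DNA, with and without a 3-cycle reconditioning
#' step (triplicates A/B/C), plus an ocean virus community at two cycle
#' numbers, and unamplified controls. Columns: `sample_set`
#' ("isolate"/"community"), `pool`, `treatment` label, `input_ng`, `cycles`
#' (0 for unamplified), `reconditioned`, `replicate`, `barcode`, `reads`
#' (post-QC read count). This table drives comparison-plan enumeration and
#' configures the simulator's treatment grid.
#'
#' @param path TSV path; defaults to the bundled table.
#' @return Data frame, one row per treatment.
#' @export
la_treatments <- function(path = system.file("extdata", "la_treatments.tsv",
                                             package = "linkamp")) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$reconditioned <- as.logical(df$reconditioned)
  df
}
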