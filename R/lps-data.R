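#' Load the LPS dendritic-cell time-course dataset
#'
#' Loader for the published mouse dendritic-cell LPS stimulation
#' time course (RNA-seq and pulsed-SILAC mass-spectrometry layers measured
#' on 3,147 shared genes; 2 conditions x 7 time points x 2 replicates).
#' The four CSV files (`rnaseq-x.csv`, `rnaseq-y.csv`, `masshl-x.csv`,
#' `masshl-y.csv`) are distributed with the original study and are not
#' bundled here; point `dir` at a local copy. Expression files are stored
#' features x samples and are transposed on read; the mass-spectrometry
#' layer is subset to the time points with a matching RNA-seq measurement.
#'
#' @param dir directory containing the four CSV files.
#' @return list with `rnaseq` ([count_table], samples x 3147 genes),
#'   `rnaseq_annot`, `masshl`, `masshl_annot`.
#' @export
load_lps_dataset <- function(dir) {
  need <- c("rnaseq-x.csv", "rnaseq-y.csv", "masshl-x.csv", "masshl-y.csv")
  paths <- file.path(dir, need)
  miss <- need[!file.exists(paths)]
  if (length(miss) > 0L) {
    stopf("LPS dataset file(s) not found in '%s': %s", dir,
          paste(miss, collapse = ", "))
  }
  rnaseq <- read_count_table(paths[1L], orientation = "samples_as_cols",
                             unit = "tpm_like")
  rnaseq_annot <- utils::read.csv(paths[2L], row.names = 1L,
                                  check.names = FALSE)
  masshl <- read_count_table(paths[3L], orientation = "samples_as_cols",
                             unit = "tpm_like")
  masshl_annot <- utils::read.csv(paths[4L], row.names = 1L,
                                  check.names = FALSE)
  # subset the MS layer to time points with a matching RNA-seq measurement
  in_both <- masshl_annot$Time
  masshl <- count_table(masshl$values[in_both, , drop = FALSE],
                        unit = masshl$unit)
  masshl_annot <- masshl_annot[in_both, , drop = FALSE]
  list(rnaseq = rnaseq, rnaseq_annot = rnaseq_annot,
       masshl = masshl, masshl_annot = masshl_annot)
}
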