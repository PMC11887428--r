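#' Bundled reference CCS tables
#'
#' Three reference tables ship with the package. `"table1"` compares
#' stepped-field and calibrated single-field drift-tube CCS
#' determinations for twelve glycan ions, with the printed percent
#' differences.  `"table2"` and `"table3"` hold computed CCS values for
#' 27 glycan charge-model systems before and after conformational
#' ensemble sampling, with printed per-method and averaged percent
#' errors.  All values are stored as printed (the per-row errors were
#' computed from unrounded calculated CCS values, so recomputing them
#' from the printed CCS columns reproduces them only to about
#' +/- 0.06).  The mannohexaose row of `"table3"` is flagged: its
#' printed stepped and averaged errors are mutually inconsistent.
#'
#' @param name `"table1"`, `"table2"` or `"table3"`.
#' @return A data frame; comment headers in the CSV describe the columns.
#' @export
glyccs_reference <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "glyccs",
                      mustWork = TRUE)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a user reference CCS table
#'
#' Accepts the same CSV schema as the bundled tables' experimental
#' columns: `analyte`, `mode` (`neg`/`pos`), `stepped_A2`, `single_A2`
#' (either may be NA, not both).  The averaged reference is the
#' arithmetic mean of the two when both exist, else the available one.
#'
#' @param path CSV file path.
#' @return Data frame with `analyte`, `mode`, `stepped_A2`, `single_A2`,
#'   `avg_A2`.
#' @export
read_reference_table <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("analyte", "mode", "stepped_A2", "single_A2")
  if (!all(need %in% names(df)))
    stop("reference CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(is.na(df$stepped_A2) & is.na(df$single_A2)))
    stop("every reference row needs at least one experimental value",
         call. = FALSE)
  df$avg_A2 <- rowMeans(df[, c("stepped_A2", "single_A2")], na.rm = TRUE)
  df
}
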