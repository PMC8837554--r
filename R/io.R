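#' Read and write summary statistics in the shared tab-delimited dialect
#'
#' Fixed header `SNP CHR BP EA OA EAF BETA SE P INFO N_CASES N_CONTROLS`,
#' plus any extra columns present.
#'
#' @param file Path.
#' @param x Summary-statistics tibble.
#' @return `read_sumstats()` returns a tibble; `write_sumstats()` returns `x`
#'   invisibly.
#' @export
read_sumstats <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE)
  assert_cols(x, c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA", "SE"),
              sprintf("'%s'", file))
  x
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(x, file) {
  readr::write_tsv(x, file)
  invisible(x)
}
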