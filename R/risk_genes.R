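#' High-risk Alzheimer's disease gene panel
#'
#' Parses the bundled panel of 28 AD high-risk gene symbols (the AHBA
#' high-risk set: A2M through SORL1) used for map correlation panels.
#' Blank lines and `#` comments are ignored; duplicates are removed while
#' preserving order.
#'
#' @param path optional path to an alternative one-symbol-per-line file.
#' @return character vector of distinct gene symbols.
#' @examples
#' length(ad_risk_genes())  # 28
#' @export
ad_risk_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ad_risk_genes.txt", package = "pmvnet")
  }
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
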