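#' Published marker counts of the study cohort
#'
#' The printed per-group counts of the molecular (mRNA/mutation) and IHC
#' comparison tables, plus the ER-negative signature counts, as packaged in
#' `inst/extdata/published_counts.csv`. `denominator` is the number of
#' assessable tumors for the item (57 for the MA markers with one missing
#' case; 53 for AR within the ER-negative subset). These counts are the
#' reference the fixture replica ([generate_fixture_replica()]) is built
#' to reproduce.
#'
#' @param table Optional filter: `"molecular"`, `"ihc"` or `"signature"`.
#' @return Data frame with columns `table`, `item`, `group`, `count`,
#'   `denominator`.
#' @export
#' @examples
#' head(published_counts("ihc"))
published_counts <- function(table = NULL) {
  path <- system.file("extdata", "published_counts.csv",
                      package = "apocrineR", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(table)) {
    table <- match.arg(table, unique(df$table))
    df <- df[df$table == table, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
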