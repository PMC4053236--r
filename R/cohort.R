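#' @keywords internal
"_PACKAGE"

#' Genes of the qRT-PCR expression panel
#'
#' The nine assayed genes: `ESR1` (estrogen receptor), `AR` (androgen
#' receptor), `FOXA1`, `ERBB2` (HER2), and the five AR-pathway genes
#' `AGR2`, `ALCAM`, `SPDEF`, `TFF3`, `UGT2B28A`. `TFF3` is the HGNC symbol
#' for the gene sometimes listed as "TTF3" in signature descriptions.
#'
#' @format Character vector of length 9.
#' @export
PANEL_GENES <- c("ESR1", "AR", "FOXA1", "ERBB2",
                 "AGR2", "ALCAM", "SPDEF", "TFF3", "UGT2B28A")

#' AR-pathway genes of the signature
#' @format Character vector of length 5.
#' @export
AR_RELATED_GENES <- c("AGR2", "ALCAM", "SPDEF", "TFF3", "UGT2B28A")

# nuclear stains are called positive at >= 10% stained cells,
# cytoplasmic stains at >= 5%
NUCLEAR_MARKERS     <- c("er", "pr", "ar", "foxa1")
CYTOPLASMIC_MARKERS <- c("gcdfp15", "ck56", "ck17", "egfr")

HER2_SCORES <- c("0", "1+", "2+", "3+")

#' Column layout of a cohort table
#'
#' One row per tumor. `ratio_<GENE>` columns hold normalized target/TBP
#' expression ratios; `ihc_<marker>_pct` columns hold percentages of stained
#' tumor cells; `her2_score` is the ASCO IHC score; `her2_ish` records the
#' in-situ-hybridization ERBB2 amplification result used to resolve 2+
#' cases; `tp53` is the yeast functional-assay (FASAY) class; `pik3ca` is
#' the hotspot mutation status; survival columns hold months and event
#' indicators. Empty cells are missing values.
#'
#' @format Character vector of column names.
#' @export
COHORT_COLUMNS <- c(
  "tumor_id", "group",
  paste0("ratio_", PANEL_GENES),
  paste0("ihc_", c(NUCLEAR_MARKERS, CYTOPLASMIC_MARKERS), "_pct"),
  "her2_score", "her2_ish", "ihc_ki67_pct",
  "tp53", "pik3ca",
  "dfs_months", "dfs_event", "os_months", "os_event"
)

#' Construct and validate a tumor cohort table
#'
#' Wraps a data frame with one row per tumor into a validated `ma_cohort`
#' object. All columns of [COHORT_COLUMNS] must be present (extra columns
#' are kept). Validation enforces the domain invariants: stain percentages
#' in \[0, 100\], expression ratios non-negative, survival times
#' non-negative with event indicators defined wherever times are, ISH
#' results only on HER2 2+ cases, and categorical columns restricted to
#' their allowed levels.
#'
#' @param df Data frame with the columns of [COHORT_COLUMNS].
#' @return The validated data frame with class `ma_cohort`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_ma = 5, n_bl = 2), seed = 1)
#' nrow(coh)
ma_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_ma_cohort(df)
  class(df) <- c("ma_cohort", "data.frame")
  df
}

validate_ma_cohort <- function(df) {
  chk_levels <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop(sprintf("invalid %s value(s): %s", what,
                   paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    }
  }
  chk_levels(df$group, c("MA", "BL", "unknown"), "group")
  chk_levels(df$her2_score, HER2_SCORES, "her2_score")
  chk_levels(df$tp53, c("functional", "nonfunctional"), "tp53")
  chk_levels(df$pik3ca, c("wild_type", "E542K", "E545K", "H1047R"), "pik3ca")

  for (g in PANEL_GENES) {
    r <- df[[paste0("ratio_", g)]]
    if (any(!is.na(r) & r < 0)) {
      stop("negative expression ratio for gene ", g, call. = FALSE)
    }
  }
  for (m in c(NUCLEAR_MARKERS, CYTOPLASMIC_MARKERS, "ki67")) {
    p <- df[[paste0("ihc_", m, "_pct")]]
    if (any(!is.na(p) & (p < 0 | p > 100))) {
      stop("IHC percentage outside [0, 100] for marker ", m, call. = FALSE)
    }
  }
  bad_ish <- !is.na(df$her2_ish) &
    (is.na(df$her2_score) | df$her2_score != "2+")
  if (any(bad_ish)) {
    stop("her2_ish may only be recorded for HER2 2+ cases (row ",
         paste(which(bad_ish), collapse = ", "), ")", call. = FALSE)
  }
  for (ep in c("dfs", "os")) {
    tm <- df[[paste0(ep, "_months")]]
    ev <- df[[paste0(ep, "_event")]]
    if (any(!is.na(tm) & tm < 0)) {
      stop("negative ", ep, " time", call. = FALSE)
    }
    if (any(!is.na(tm) & is.na(ev))) {
      stop(ep, " event indicator missing where time is present", call. = FALSE)
    }
  }
  invisible(df)
}

#' Call an immunohistochemical marker positive or negative
#'
#' Nuclear stains (ER, PR, AR, FOXA1) are positive when at least 10% of
#' tumor cells stain; cytoplasmic stains (GCDFP15, CK5/6, CK17, EGFR) when
#' at least 5% stain. Missing percentages propagate to a missing call.
#' HER2 (scored per ASCO guidelines) and Ki67 (kept continuous) are not
#' handled here; see [call_her2()].
#'
#' @param cohort An [ma_cohort] data frame (or any data frame carrying the
#'   `ihc_<marker>_pct` column).
#' @param marker One of `"er"`, `"pr"`, `"ar"`, `"foxa1"`, `"gcdfp15"`,
#'   `"ck56"`, `"ck17"`, `"egfr"`.
#' @return Factor with levels `positive`/`negative`; `NA` where the stain
#'   was not assessed.
#' @export
#' @examples
#' coh <- generate_fixture_replica()
#' table(call_ihc_marker(coh, "ar"), coh$group, useNA = "ifany")
call_ihc_marker <- function(cohort, marker) {
  if (marker %in% NUCLEAR_MARKERS) {
    thr <- 10
  } else if (marker %in% CYTOPLASMIC_MARKERS) {
    thr <- 5
  } else {
    stop("unknown IHC marker: '", marker,
         "' (HER2 and Ki67 are not thresholded here)", call. = FALSE)
  }
  pct <- cohort[[paste0("ihc_", marker, "_pct")]]
  factor(ifelse(is.na(pct), NA, ifelse(pct >= thr, "positive", "negative")),
         levels = c("positive", "negative"))
}

#' Call HER2 status from the ASCO score and ISH resolution
#'
#' Positive for score 3+, or for score 2+ with ERBB2 amplification shown by
#' in situ hybridization; negative for 0/1+ and for 2+ cases that are
#' ISH-negative or unresolved. Missing scores propagate.
#'
#' @param cohort Data frame with `her2_score` and `her2_ish` columns.
#' @return Factor with levels `positive`/`negative`, `NA` for missing score.
#' @export
call_her2 <- function(cohort) {
  score <- cohort$her2_score
  ish <- cohort$her2_ish
  pos <- score == "3+" | (score == "2+" & !is.na(ish) & ish)
  factor(ifelse(is.na(score), NA, ifelse(pos, "positive", "negative")),
         levels = c("positive", "negative"))
}

#' Subset a cohort to the IHC ER-negative tumors
#'
#' The composite diagnostic signature is defined in the ER-negative
#' setting; this returns the tumors whose ER immunostain is called
#' negative (below 10% stained nuclei). Tumors with missing ER are dropped.
#'
#' @param cohort An [ma_cohort].
#' @return The ER-negative subset, still an `ma_cohort`.
#' @export
er_negative_subset <- function(cohort) {
  er <- call_ihc_marker(cohort, "er")
  out <- cohort[!is.na(er) & er == "negative", , drop = FALSE]
  class(out) <- c("ma_cohort", "data.frame")
  out
}

NUMERIC_COHORT_COLUMNS <- c(
  paste0("ratio_", PANEL_GENES),
  paste0("ihc_", c(NUCLEAR_MARKERS, CYTOPLASMIC_MARKERS, "ki67"), "_pct"),
  "dfs_months", "os_months"
)

#' Read a cohort table from delimited text
#'
#' Reads a UTF-8 comma- (default) or tab-delimited file with one row per
#' tumor and the columns documented in [COHORT_COLUMNS]. Empty cells are
#' missing. Unknown columns are ignored with a warning; missing mandatory
#' columns or unparsable numeric cells raise an error naming the offender.
#'
#' @param path File path.
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return An [ma_cohort].
#' @export
read_cohort <- function(path, delim = c(",", "\t")) {
  delim <- match.arg(delim)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", na.strings = "",
                           check.names = FALSE, quote = "\"",
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[COHORT_COLUMNS]
  }
  for (col in NUMERIC_COHORT_COLUMNS) {
    x <- raw[[col]]
    num <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(num)
    if (any(bad)) {
      stop(sprintf("unparsable numeric value '%s' in column %s (tumor %s)",
                   x[which(bad)[1]], col, raw$tumor_id[which(bad)[1]]),
           call. = FALSE)
    }
    raw[[col]] <- num
  }
  for (col in c("dfs_event", "os_event", "her2_ish")) {
    x <- raw[[col]]
    lg <- rep(NA, length(x))
    lg[!is.na(x) & x %in% c("TRUE", "true", "1")] <- TRUE
    lg[!is.na(x) & x %in% c("FALSE", "false", "0")] <- FALSE
    bad <- !is.na(x) & is.na(lg)
    if (any(bad)) {
      stop(sprintf("unparsable logical value '%s' in column %s (tumor %s)",
                   x[which(bad)[1]], col, raw$tumor_id[which(bad)[1]]),
           call. = FALSE)
    }
    raw[[col]] <- lg
  }
  ma_cohort(raw)
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: writing then reading reproduces the cohort
#' exactly, including missingness.
#'
#' @param cohort An [ma_cohort].
#' @param path Output file path.
#' @param delim Field delimiter, `","` or `"\t"`.
#' @export
write_cohort <- function(cohort, path, delim = c(",", "\t")) {
  delim <- match.arg(delim)
  df <- as.data.frame(cohort)[COHORT_COLUMNS]
  utils::write.table(df, path, sep = delim, na = "", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
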