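subtype_criteria <- function(panel, cutoffs) {
  need <- c("ESR1", "AR", "FOXA1")
  miss <- need[is.na(panel[need])]
  if (length(miss) > 0) {
    stop("cannot call subtype: missing ratio for ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  related <- panel[AR_RELATED_GENES]
  # missing AR-related values count against positivity, never toward it
  list(
    esr1_neg = unname(panel["ESR1"] <= cutoffs[["ESR1"]]),
    ar_pos = unname(panel["AR"] > cutoffs[["AR"]]),
    foxa1_pos = unname(panel["FOXA1"] > cutoffs[["FOXA1"]]),
    erbb2_pos = if (is.na(panel["ERBB2"])) NA else
      unname(panel["ERBB2"] > cutoffs[["ERBB2"]]),
    ar_related_count = sum(!is.na(related) &
                             related > cutoffs[AR_RELATED_GENES])
  )
}

new_subtype_call <- function(call, criteria, cutoffs) {
  structure(list(call = call, criteria = criteria, cutoffs = cutoffs),
            class = "ma_subtype_call")
}

#' @export
print.ma_subtype_call <- function(x, ...) {
  cat("Subtype call:", x$call, "\n")
  cat(sprintf(
    "  ESR1-negative: %s | AR-positive: %s | FOXA1-positive: %s | AR-related genes over cutoff: %d/5\n",
    x$criteria$esr1_neg, x$criteria$ar_pos, x$criteria$foxa1_pos,
    x$criteria$ar_related_count))
  invisible(x)
}

#' Molecular apocrine qRT-PCR signature call
#'
#' A tumor is called molecular apocrine (MA) when its expression panel
#' shows absence of ESR1 overexpression (ratio at or below the ER cutoff),
#' AR and FOXA1 overexpression (ratios above their cutoffs), and
#' overexpression of at least three of the five AR-pathway genes (AGR2,
#' ALCAM, SPDEF, TFF3, UGT2B28A). Tumors failing the MA criteria are
#' routed to the basal-like candidate rule (lack of ESR1, FOXA1 and ERBB2
#' expression; AR not required, since a minority of basal-like tumors
#' express AR mRNA) and otherwise left unclassified.
#'
#' @param panel Named numeric vector of expression ratios over
#'   [PANEL_GENES] (see [panel_from_ct()]); `NA` allowed except for ESR1,
#'   AR and FOXA1.
#' @param cutoffs Named ratio-scale cutoffs, e.g. [default_cutoffs()] or
#'   [derive_cutoffs()].
#' @return An `ma_subtype_call`: list with `call` (one of `"MA"`,
#'   `"BL_candidate"`, `"unclassified"`), the per-criterion values in
#'   `criteria`, and the cutoffs used.
#' @export
#' @examples
#' p <- c(ESR1 = 5, AR = 2207, FOXA1 = 660, ERBB2 = 40, AGR2 = 300,
#'        ALCAM = 300, SPDEF = 300, TFF3 = 300, UGT2B28A = 50)
#' classify_ma(p, default_cutoffs())$call
classify_ma <- function(panel, cutoffs = default_cutoffs()) {
  cr <- subtype_criteria(panel, cutoffs)
  is_ma <- cr$esr1_neg && cr$ar_pos && cr$foxa1_pos && cr$ar_related_count >= 3
  call <- if (is_ma) {
    "MA"
  } else if (!is.na(cr$erbb2_pos) && cr$esr1_neg && !cr$foxa1_pos &&
             !cr$erbb2_pos) {
    "BL_candidate"
  } else {
    "unclassified"
  }
  new_subtype_call(call, cr, cutoffs)
}

#' Basal-like candidate call
#'
#' Same decision logic as [classify_ma()] but requires the ERBB2 ratio to
#' be present, since the basal-like rule (ESR1-negative, FOXA1-negative,
#' ERBB2-negative) cannot be evaluated without it.
#'
#' @inheritParams classify_ma
#' @return An `ma_subtype_call`.
#' @export
classify_bl_candidate <- function(panel, cutoffs = default_cutoffs()) {
  if (is.na(panel["ERBB2"])) {
    stop("cannot evaluate the basal-like rule: missing ERBB2 ratio",
         call. = FALSE)
  }
  classify_ma(panel, cutoffs)
}

#' Classify every tumor of a cohort
#'
#' Applies [classify_ma()] row-wise; tumors whose mandatory ratios (ESR1,
#' AR, FOXA1) are missing are returned as `NA` calls rather than raising.
#'
#' @param cohort An [ma_cohort].
#' @param cutoffs Ratio-scale cutoffs.
#' @return Data frame with `tumor_id`, `call`, the per-criterion columns
#'   and `ar_related_count`.
#' @export
classify_cohort <- function(cohort, cutoffs = default_cutoffs()) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    panel <- stats::setNames(
      as.numeric(cohort[i, paste0("ratio_", PANEL_GENES)]), PANEL_GENES)
    res <- tryCatch(classify_ma(panel, cutoffs), error = function(e) NULL)
    if (is.null(res)) {
      data.frame(tumor_id = cohort$tumor_id[i], call = NA_character_,
                 esr1_neg = NA, ar_pos = NA, foxa1_pos = NA,
                 ar_related_count = NA_integer_)
    } else {
      data.frame(tumor_id = cohort$tumor_id[i], call = res$call,
                 esr1_neg = res$criteria$esr1_neg,
                 ar_pos = res$criteria$ar_pos,
                 foxa1_pos = res$criteria$foxa1_pos,
                 ar_related_count = res$criteria$ar_related_count)
    }
  })
  do.call(rbind, rows)
}

#' Composite IHC rule: HER2(3+) OR GCDFP15(+)
#'
#' The immunohistochemical signature of molecular apocrine tumors in the
#' ER-negative setting: positive when the HER2 immunostain scores 3+ or
#' GCDFP15 is positive. Only the 3+ score counts on the HER2 side
#' (ISH-resolved 2+ cases do not enter the rule); a missing component is
#' treated as negative for the OR, and a tumor missing both raises an
#' error.
#'
#' @param her2_score Character vector of ASCO scores (`"0"`, `"1+"`,
#'   `"2+"`, `"3+"`), `NA` allowed.
#' @param gcdfp15 Factor/character vector of GCDFP15 calls
#'   (`positive`/`negative`), `NA` allowed.
#' @return Logical vector: rule positivity per tumor.
#' @export
#' @examples
#' ihc_combined_rule(c("3+", "1+", "1+"),
#'                   c("negative", "positive", "negative"))
ihc_combined_rule <- function(her2_score, gcdfp15) {
  gcdfp15 <- as.character(gcdfp15)
  both_missing <- is.na(her2_score) & is.na(gcdfp15)
  if (any(both_missing)) {
    stop("both HER2 score and GCDFP15 missing for tumor(s) at position ",
         paste(which(both_missing), collapse = ", "), call. = FALSE)
  }
  (!is.na(her2_score) & her2_score == "3+") |
    (!is.na(gcdfp15) & gcdfp15 == "positive")
}
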