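#' Normalized expression ratio from Ct measurements
#'
#' Relative quantification of a target gene against the TBP reference gene:
#' the ratio is `scale * efficiency^(ct_reference - ct_target)`. With a
#' perfectly efficient PCR (efficiency 2, doubling per cycle) and scale 1
#' this is the classical 2^-dCt quantity; the default scale of 1000 puts
#' ratios on the order of the positivity cutoffs used for the signature
#' (ER 20, HER2 7, AR/FOXA1 100). Lower Ct means higher expression, so the
#' ratio is monotone decreasing in `ct_target`.
#'
#' @param ct_target Cycle threshold of the target gene (vectorized).
#' @param ct_reference Cycle threshold of the reference gene (TBP).
#' @param efficiency Amplification efficiency per cycle, in (1, 2].
#' @param scale Positive multiplier applied to the ratio.
#' @return Numeric vector of non-negative ratios; `NA` where either Ct is
#'   missing.
#' @export
#' @examples
#' normalized_ratio(25, 25, scale = 1)        # equal Ct -> 1
#' normalized_ratio(24, 25, scale = 1000)     # one cycle earlier -> 2000
normalized_ratio <- function(ct_target, ct_reference,
                             efficiency = 2, scale = 1000) {
  if (any(efficiency <= 1 | efficiency > 2)) {
    stop("amplification efficiency must be in (1, 2]", call. = FALSE)
  }
  if (any(scale <= 0)) stop("scale must be positive", call. = FALSE)
  if (any(!is.na(ct_target) & ct_target <= 0) ||
      any(!is.na(ct_reference) & ct_reference <= 0)) {
    stop("cycle numbers must be positive", call. = FALSE)
  }
  scale * efficiency^(ct_reference - ct_target)
}

#' Build an expression panel from per-gene Ct measurements
#'
#' Averages technical replicates arithmetically on the Ct scale is out of
#' scope; at most one measurement per gene is accepted. Genes without a
#' measurement are missing in the returned panel.
#'
#' @param measurements Data frame with columns `gene`, `ct_target`,
#'   `ct_tbp`, and optionally `efficiency` and `scale`.
#' @param efficiency,scale Defaults used where the data frame does not
#'   carry its own columns.
#' @return Named numeric vector over [PANEL_GENES] (an expression panel);
#'   `NA` for unmeasured genes.
#' @export
panel_from_ct <- function(measurements, efficiency = 2, scale = 1000) {
  stopifnot(is.data.frame(measurements))
  panel <- stats::setNames(rep(NA_real_, length(PANEL_GENES)), PANEL_GENES)
  if (nrow(measurements) == 0) return(panel)
  required <- c("gene", "ct_target", "ct_tbp")
  miss <- setdiff(required, names(measurements))
  if (length(miss) > 0) {
    stop("measurement table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(measurements$gene, PANEL_GENES)
  if (length(unknown) > 0) {
    stop("unknown panel gene(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(measurements$gene[duplicated(measurements$gene)])
  if (length(dup) > 0) {
    stop("duplicate measurement for gene(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  eff <- if ("efficiency" %in% names(measurements)) {
    measurements$efficiency
  } else {
    efficiency
  }
  sc <- if ("scale" %in% names(measurements)) measurements$scale else scale
  panel[measurements$gene] <-
    normalized_ratio(measurements$ct_target, measurements$ct_tbp, eff, sc)
  panel
}
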