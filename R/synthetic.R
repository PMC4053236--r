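gene_component <- function(neg_mean, neg_sd, pos_mean, pos_sd,
                           p_pos_ma, p_pos_bl) {
  list(neg = c(mean = neg_mean, sd = neg_sd),
       pos = c(mean = pos_mean, sd = pos_sd),
       p_pos_ma = p_pos_ma, p_pos_bl = p_pos_bl)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the 58 molecular-apocrine /
#' 13 basal-like cohort: per-gene log10-ratio components place the
#' basal-like AR population around a median ratio of 45 and the MA AR
#' population around 1500; IHC marker positivity probabilities equal the
#' observed cohort frequencies; within ER-negative MA tumors the
#' HER2(3+)/GCDFP15 joint distribution is constrained so that the combined
#' rule is positive with probability 51/54; TP53 is nonfunctional in 50%
#' of MA and all BL tumors; PIK3CA carries a hotspot mutation in 19% of MA
#' and no BL tumors; survival is exponential with rates calibrated so the
#' analytic 5-year survival equals the reported values (DFS 66%/79%, OS
#' 77%/73%), under uniform administrative censoring.
#'
#' @param n_ma,n_bl Group sizes (non-negative; at least one tumor total).
#' @param expression Named list of per-gene component settings (see the
#'   default for the structure).
#' @param ihc_p_ma,ihc_p_bl Named positivity probabilities for the
#'   independent IHC markers.
#' @param p_her2_3plus,p_gcdfp15,p_combined Marginal and union
#'   probabilities of HER2(3+) and GCDFP15(+) within ER-negative MA
#'   tumors; the implied 2x2 cell probabilities must be valid.
#' @param p_her2_2plus_given_not3 Probability that a non-3+ MA tumor
#'   scores 2+; `p_ish_amplified` the amplification probability of a 2+.
#' @param s5_dfs,s5_os Named 5-year survival targets per group.
#' @param censor_max Upper bound of the uniform administrative censoring
#'   time (months).
#' @param p_missing Per-marker missingness probabilities in the MA group.
#' @param p_missing_erbb2_mrna Missingness of the ERBB2 ratio in MA.
#' @param ki67 Mean/sd of the (truncated) Ki67 percentage per group.
#' @return A list of class `ma_cohort_config`.
#' @export
cohort_config <- function(
    n_ma = 58L, n_bl = 13L,
    expression = list(
      ESR1 = gene_component(log10(3), 0.25, log10(500), 0.30, 0, 0),
      AR = gene_component(log10(45), 0.25, log10(1500), 0.30, 1, 2 / 13),
      FOXA1 = gene_component(log10(25), 0.30, log10(600), 0.25, 1, 0),
      ERBB2 = gene_component(log10(2), 0.30, log10(40), 0.40, 38 / 56, 0),
      AGR2 = gene_component(1.0, 0.30, 2.5, 0.35, 0.95, 0.08),
      ALCAM = gene_component(1.0, 0.30, 2.5, 0.35, 0.95, 0.08),
      SPDEF = gene_component(1.0, 0.30, 2.5, 0.35, 0.95, 0.08),
      TFF3 = gene_component(1.0, 0.30, 2.5, 0.35, 0.95, 0.08),
      UGT2B28A = gene_component(1.0, 0.30, 2.5, 0.35, 0.95, 0.08)),
    ihc_p_ma = c(er = 4 / 58, pr = 2 / 58, foxa1 = 52 / 58, ar = 33 / 57,
                 egfr = 17 / 57, ck56 = 6 / 57, ck17 = 3 / 57),
    ihc_p_bl = c(er = 0, pr = 0, foxa1 = 4 / 13, ar = 0,
                 egfr = 9 / 13, ck56 = 8 / 13, ck17 = 8 / 13),
    p_her2_3plus = 39 / 54, p_gcdfp15 = 33 / 54, p_combined = 51 / 54,
    p_her2_2plus_given_not3 = 5 / 19, p_ish_amplified = 4 / 5,
    p_tp53_nonfunctional = c(MA = 0.5, BL = 1),
    p_pik3ca = list(MA = c(wild_type = 47 / 58, E542K = 1 / 58,
                           E545K = 0, H1047R = 10 / 58),
                    BL = c(wild_type = 1, E542K = 0, E545K = 0, H1047R = 0)),
    s5_dfs = c(MA = 0.66, BL = 0.79),
    s5_os = c(MA = 0.77, BL = 0.73),
    censor_max = 180,
    p_missing = c(ar = 1 / 58, egfr = 1 / 58, ck56 = 1 / 58, ck17 = 1 / 58),
    p_missing_erbb2_mrna = 2 / 58,
    ki67 = list(MA = c(mean = 30, sd = 18), BL = c(mean = 50, sd = 20))) {

  cfg <- list(n_ma = as.integer(n_ma), n_bl = as.integer(n_bl),
              expression = expression,
              ihc_p_ma = ihc_p_ma, ihc_p_bl = ihc_p_bl,
              p_her2_3plus = p_her2_3plus, p_gcdfp15 = p_gcdfp15,
              p_combined = p_combined,
              p_her2_2plus_given_not3 = p_her2_2plus_given_not3,
              p_ish_amplified = p_ish_amplified,
              p_tp53_nonfunctional = p_tp53_nonfunctional,
              p_pik3ca = p_pik3ca,
              s5_dfs = s5_dfs, s5_os = s5_os, censor_max = censor_max,
              p_missing = p_missing,
              p_missing_erbb2_mrna = p_missing_erbb2_mrna,
              ki67 = ki67)
  validate_cohort_config(cfg)
  class(cfg) <- "ma_cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_ma < 0 || cfg$n_bl < 0 || cfg$n_ma + cfg$n_bl < 1) {
    stop("cohort sizes must be non-negative with at least one tumor",
         call. = FALSE)
  }
  probs <- c(cfg$ihc_p_ma, cfg$ihc_p_bl, cfg$p_her2_3plus, cfg$p_gcdfp15,
             cfg$p_combined, cfg$p_her2_2plus_given_not3,
             cfg$p_ish_amplified, cfg$p_tp53_nonfunctional,
             unlist(cfg$p_pik3ca), cfg$s5_dfs, cfg$s5_os,
             cfg$p_missing, cfg$p_missing_erbb2_mrna)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  # the HER2 x GCDFP15 union constraint must define a valid joint law
  if (cfg$p_combined < max(cfg$p_her2_3plus, cfg$p_gcdfp15) - 1e-12) {
    stop("infeasible joint constraint: the union probability of ",
         "HER2(3+)/GCDFP15(+) is below one of its marginals", call. = FALSE)
  }
  if (cfg$p_combined > cfg$p_her2_3plus + cfg$p_gcdfp15 + 1e-12) {
    stop("infeasible joint constraint: the union probability exceeds the ",
         "sum of the HER2(3+)/GCDFP15(+) marginals", call. = FALSE)
  }
  for (grp in c("MA", "BL")) {
    if (abs(sum(cfg$p_pik3ca[[grp]]) - 1) > 1e-9) {
      stop("PIK3CA status probabilities must sum to 1 for group ", grp,
           call. = FALSE)
    }
    # exponential rates are derived from the 5-year targets, so the
    # analytic S(60) must reproduce them (guards user-supplied overrides)
    for (tg in list(cfg$s5_dfs[[grp]], cfg$s5_os[[grp]])) {
      rate <- -log(tg) / 60
      if (abs(exp(-60 * rate) - tg) > 0.02) {
        stop("survival calibration failed for group ", grp, call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

her2_gcdfp15_cells <- function(cfg) {
  both <- cfg$p_her2_3plus + cfg$p_gcdfp15 - cfg$p_combined
  c(both = both,
    her2_only = cfg$p_her2_3plus - both,
    gcdfp15_only = cfg$p_gcdfp15 - both,
    neither = 1 - cfg$p_combined)
}

rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 100) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

draw_gene <- function(n, comp, p_pos) {
  pos <- stats::runif(n) < p_pos
  mean <- ifelse(pos, comp$pos["mean"], comp$neg["mean"])
  sd <- ifelse(pos, comp$pos["sd"], comp$neg["sd"])
  10^stats::rnorm(n, mean, sd)
}

nuclear_pct <- function(pos) {
  ifelse(pos, stats::runif(length(pos), 10, 90),
         stats::runif(length(pos), 0, 9))
}
cytoplasmic_pct <- function(pos) {
  ifelse(pos, stats::runif(length(pos), 5, 90),
         stats::runif(length(pos), 0, 4))
}

generate_group <- function(cfg, group, n, id_prefix) {
  ma <- group == "MA"
  p_ihc <- if (ma) cfg$ihc_p_ma else cfg$ihc_p_bl
  df <- data.frame(tumor_id = sprintf("%s%03d", id_prefix, seq_len(n)),
                   group = rep(group, n), stringsAsFactors = FALSE)

  for (g in PANEL_GENES) {
    comp <- cfg$expression[[g]]
    df[[paste0("ratio_", g)]] <-
      draw_gene(n, comp, if (ma) comp$p_pos_ma else comp$p_pos_bl)
  }
  if (ma && cfg$p_missing_erbb2_mrna > 0) {
    df$ratio_ERBB2[stats::runif(n) < cfg$p_missing_erbb2_mrna] <- NA
  }

  er_pos <- stats::runif(n) < p_ihc[["er"]]
  pr_pos <- stats::runif(n) < p_ihc[["pr"]]
  if (ma) {
    # HER2(3+) and GCDFP15(+) are drawn jointly within ER-negative MA so
    # that the combined rule holds with the configured union probability;
    # ER-positive MA tumors carry neither (this preserves the marginals)
    cells <- her2_gcdfp15_cells(cfg)
    cell <- sample(names(cells), n, replace = TRUE, prob = cells)
    her2_3 <- !er_pos & cell %in% c("both", "her2_only")
    gcdfp15_pos <- !er_pos & cell %in% c("both", "gcdfp15_only")
  } else {
    her2_3 <- rep(FALSE, n)
    gcdfp15_pos <- rep(FALSE, n)
  }
  score <- rep("0", n)
  ish <- rep(NA, n)
  score[her2_3] <- "3+"
  if (ma) {
    two_plus <- !her2_3 & stats::runif(n) < cfg$p_her2_2plus_given_not3
    score[two_plus] <- "2+"
    ish[two_plus] <- stats::runif(sum(two_plus)) < cfg$p_ish_amplified
    score[!her2_3 & !two_plus] <-
      sample(c("0", "1+"), sum(!her2_3 & !two_plus), replace = TRUE)
  }

  df$ihc_er_pct <- nuclear_pct(er_pos)
  df$ihc_pr_pct <- nuclear_pct(pr_pos)
  df$ihc_ar_pct <- nuclear_pct(stats::runif(n) < p_ihc[["ar"]])
  df$ihc_foxa1_pct <- nuclear_pct(stats::runif(n) < p_ihc[["foxa1"]])
  df$ihc_gcdfp15_pct <- cytoplasmic_pct(gcdfp15_pos)
  df$ihc_ck56_pct <- cytoplasmic_pct(stats::runif(n) < p_ihc[["ck56"]])
  df$ihc_ck17_pct <- cytoplasmic_pct(stats::runif(n) < p_ihc[["ck17"]])
  df$ihc_egfr_pct <- cytoplasmic_pct(stats::runif(n) < p_ihc[["egfr"]])
  df$her2_score <- score
  df$her2_ish <- ish
  ki <- cfg$ki67[[group]]
  df$ihc_ki67_pct <- rtrunc_norm(n, ki[["mean"]], ki[["sd"]], 0, 90)

  if (ma) {
    for (m in names(cfg$p_missing)) {
      col <- paste0("ihc_", m, "_pct")
      df[[col]][stats::runif(n) < cfg$p_missing[[m]]] <- NA
    }
  }

  df$tp53 <- ifelse(stats::runif(n) < cfg$p_tp53_nonfunctional[[group]],
                    "nonfunctional", "functional")
  pk <- cfg$p_pik3ca[[group]]
  df$pik3ca <- sample(names(pk), n, replace = TRUE, prob = pk)

  for (ep in c("dfs", "os")) {
    target <- if (ep == "dfs") cfg$s5_dfs[[group]] else cfg$s5_os[[group]]
    rate <- -log(target) / 60
    ev_time <- stats::rexp(n, rate)
    cens <- stats::runif(n, 0, cfg$censor_max)
    df[[paste0(ep, "_months")]] <- pmin(ev_time, cens)
    df[[paste0(ep, "_event")]] <- ev_time <= cens
  }
  df
}

#' Generate a synthetic tumor cohort
#'
#' Draws a cohort with the statistical structure the analysis pipeline
#' assumes (see [cohort_config()]): group labels are recorded as ground
#' truth, expression ratios come from subtype-conditional lognormal
#' components, IHC calls from the configured (and jointly constrained)
#' positivity probabilities, and survival from the calibrated
#' event-plus-censoring model. Identical seeds give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return An [ma_cohort] of `n_ma + n_bl` tumors.
#' @export
#' @examples
#' coh <- generate_cohort(seed = 1)
#' table(coh$group)
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  parts <- list()
  if (config$n_ma > 0) {
    parts$ma <- generate_group(config, "MA", config$n_ma, "ma")
  }
  if (config$n_bl > 0) {
    parts$bl <- generate_group(config, "BL", config$n_bl, "bl")
  }
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  ma_cohort(df[COHORT_COLUMNS])
}

#' Deterministic replica of the published cohort's marker tables
#'
#' A synthetic reconstruction of the 71-tumor cohort (58 molecular
#' apocrine, 13 basal-like) whose marker calls exactly reproduce every
#' printed marginal count: ER(-) 54, PR(-) 56, HER2(3+) 39 (plus five 2+
#' cases, four ISH-amplified), GCDFP15(+) 33, AR(+) 33/57 assessable,
#' FOXA1(+) 52, EGFR(-) 40/57, CK5/6(-) 51/57, CK17(-) 54/57 among MA;
#' and within the 67 ER-IHC-negative tumors (use [er_negative_subset()])
#' the combined HER2(3+)-or-GCDFP15(+) rule positive in 51 of 54 MA and
#' 0 of 13 BL, with AR positive in 31 of 53 assessable MA. One ER-negative
#' HER2(3+) MA tumor carries the missing AR/EGFR/CK5-6/CK17 values. Cell
#' assignments not fixed by the printed counts (the joint layout of
#' markers across tumors) are a documented reconstruction: stain
#' percentages are representative constants, not measured values, and
#' survival columns are empty since no individual follow-up data are
#' published.
#'
#' @return An [ma_cohort] of 71 tumors.
#' @export
#' @examples
#' coh <- generate_fixture_replica()
#' ern <- er_negative_subset(coh)
#' table(ihc_combined_rule(ern$her2_score, call_ihc_marker(ern, "gcdfp15")),
#'       ern$group)
generate_fixture_replica <- function() {
  n_ma <- 58
  idx <- seq_len(n_ma)
  in_set <- function(i) idx %in% i

  ma <- data.frame(tumor_id = sprintf("ma%03d", idx), group = "MA",
                   stringsAsFactors = FALSE)
  # mRNA ratios: representative values on the reported means
  ar_ihc_pos <- in_set(c(1, 2, 5:35))
  foxa1_ihc_neg <- in_set(53:58)
  ma$ratio_ESR1 <- 5
  ma$ratio_AR <- ifelse(ar_ihc_pos, 2207, 1062)
  ma$ratio_FOXA1 <- ifelse(foxa1_ihc_neg, 524, 660)
  ma$ratio_ERBB2 <- ifelse(in_set(5:42), 40, ifelse(in_set(43:44), NA, 2))
  ma$ratio_AGR2 <- 300
  ma$ratio_ALCAM <- 300
  ma$ratio_SPDEF <- 300
  ma$ratio_TFF3 <- 300
  ma$ratio_UGT2B28A <- 150
  # IHC: ER+ tumors are 1-4; the ER(-) HER2/GCDFP15 joint layout is
  # 21 both (5-25), 18 HER2(3+) only (26-43), 12 GCDFP15 only (44-55),
  # 3 neither (56-58), reproducing the 51/54 combined-rule count
  ma$ihc_er_pct <- ifelse(in_set(1:4), 80, 0)
  ma$ihc_pr_pct <- ifelse(in_set(1:2), 80, 0)
  ma$ihc_ar_pct <- ifelse(ar_ihc_pos, 80, ifelse(in_set(43), NA, 0))
  ma$ihc_foxa1_pct <- ifelse(foxa1_ihc_neg, 0, 80)
  ma$ihc_gcdfp15_pct <- ifelse(in_set(c(5:25, 44:55)), 50, 0)
  ma$ihc_ck56_pct <- ifelse(in_set(5:10), 50, ifelse(in_set(43), NA, 0))
  ma$ihc_ck17_pct <- ifelse(in_set(5:7), 50, ifelse(in_set(43), NA, 0))
  ma$ihc_egfr_pct <- ifelse(in_set(5:21), 50, ifelse(in_set(43), NA, 0))
  ma$her2_score <- ifelse(in_set(5:43), "3+",
                          ifelse(in_set(44:48), "2+",
                                 ifelse(in_set(c(1, 2, 49:55)), "1+", "0")))
  ma$her2_ish <- ifelse(in_set(44:47), TRUE, ifelse(in_set(48), FALSE, NA))
  ma$ihc_ki67_pct <- 30
  ma$tp53 <- ifelse(in_set(1:29), "functional", "nonfunctional")
  ma$pik3ca <- ifelse(in_set(1), "E542K",
                      ifelse(in_set(2:11), "H1047R", "wild_type"))

  n_bl <- 13
  jdx <- seq_len(n_bl)
  bl <- data.frame(tumor_id = sprintf("bl%03d", jdx), group = "BL",
                   stringsAsFactors = FALSE)
  bl$ratio_ESR1 <- 5
  bl$ratio_AR <- ifelse(jdx <= 2, 150, 45)
  bl$ratio_FOXA1 <- 30
  bl$ratio_ERBB2 <- 2
  bl$ratio_AGR2 <- 10
  bl$ratio_ALCAM <- 10
  bl$ratio_SPDEF <- 10
  bl$ratio_TFF3 <- 10
  bl$ratio_UGT2B28A <- 10
  bl$ihc_er_pct <- 0
  bl$ihc_pr_pct <- 0
  bl$ihc_ar_pct <- 0
  bl$ihc_foxa1_pct <- ifelse(jdx <= 4, 80, 0)
  bl$ihc_gcdfp15_pct <- 0
  bl$ihc_ck56_pct <- ifelse(jdx <= 8, 50, 0)
  bl$ihc_ck17_pct <- ifelse(jdx <= 8, 50, 0)
  bl$ihc_egfr_pct <- ifelse(jdx <= 9, 50, 0)
  bl$her2_score <- "0"
  bl$her2_ish <- NA
  bl$ihc_ki67_pct <- 50
  bl$tp53 <- "nonfunctional"
  bl$pik3ca <- "wild_type"

  df <- rbind(ma, bl)
  for (col in c("dfs_months", "os_months")) df[[col]] <- NA_real_
  for (col in c("dfs_event", "os_event")) df[[col]] <- NA
  df$her2_ish <- as.logical(df$her2_ish)
  rownames(df) <- NULL
  ma_cohort(df[COHORT_COLUMNS])
}
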