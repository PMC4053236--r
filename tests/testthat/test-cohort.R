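test_that("IHC marker thresholds are inclusive at the boundary", {
  df <- generate_fixture_replica()[1:4, ]
  df$ihc_ar_pct <- c(10, 9.99, NA, 50)
  df$ihc_gcdfp15_pct <- c(5, 4.9, NA, 80)
  expect_equal(as.character(call_ihc_marker(df, "ar")),
               c("positive", "negative", NA, "positive"))
  expect_equal(as.character(call_ihc_marker(df, "gcdfp15")),
               c("positive", "negative", NA, "positive"))
  expect_error(call_ihc_marker(df, "ki67"), "ki67")
  expect_error(call_ihc_marker(df, "tp53"), "tp53")
})

test_that("HER2 calls follow the ASCO score with ISH resolution of 2+", {
  df <- data.frame(her2_score = c("3+", "2+", "2+", "2+", "1+", "0", NA),
                   her2_ish = c(NA, TRUE, FALSE, NA, NA, NA, NA))
  expect_equal(as.character(call_her2(df)),
               c("positive", "positive", "negative", "negative",
                 "negative", "negative", NA))
})

test_that("cohort I/O round-trips losslessly in both dialects", {
  coh <- generate_cohort(cohort_config(n_ma = 3, n_bl = 2), seed = 5)
  for (delim in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_cohort(coh, path, delim = delim)
    back <- read_cohort(path, delim = delim)
    expect_equal(as.data.frame(back), as.data.frame(coh),
                 tolerance = 1e-12)
  }
})

test_that("cohort reader validates columns and numeric cells", {
  coh <- generate_cohort(cohort_config(n_ma = 3, n_bl = 2), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")

  write_cohort(coh, path)
  txt <- readLines(path)
  writeLines(gsub("^tumor_id", "id", txt), path)
  expect_error(read_cohort(path), "tumor_id")

  write_cohort(coh, path)
  txt <- readLines(path)
  writeLines(paste0(txt, c(",surprise", rep(",1", length(txt) - 1))), path)
  expect_warning(ignored <- read_cohort(path), "surprise")

  bad <- coh
  bad$ihc_ki67_pct <- as.character(bad$ihc_ki67_pct)
  bad$ihc_ki67_pct[2] <- "high"
  utils::write.table(as.data.frame(bad), path, sep = ",", na = "",
                     row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(path), "ihc_ki67_pct")
  expect_error(read_cohort(path), coh$tumor_id[2])
})

test_that("cohort validation enforces the domain invariants", {
  coh <- generate_fixture_replica()
  bad <- as.data.frame(coh); bad$ihc_er_pct[1] <- 150
  expect_error(ma_cohort(bad), "\\[0, 100\\]")
  bad <- as.data.frame(coh); bad$ratio_AR[1] <- -2
  expect_error(ma_cohort(bad), "negative expression ratio")
  bad <- as.data.frame(coh); bad$her2_ish[1] <- TRUE  # a 1+ tumor
  expect_error(ma_cohort(bad), "2\\+")
  bad <- as.data.frame(coh); bad$dfs_months[1] <- -1; bad$dfs_event[1] <- TRUE
  expect_error(ma_cohort(bad), "negative dfs time")
  bad <- as.data.frame(coh); bad$os_months[1] <- 12
  expect_error(ma_cohort(bad), "event indicator")
})

test_that("fixture replica reproduces every printed marker count", {
  coh <- generate_fixture_replica()
  expect_equal(as.vector(table(coh$group)[c("MA", "BL")]), c(58, 13))
  ma <- coh[coh$group == "MA", ]
  bl <- coh[coh$group == "BL", ]
  cnt <- function(df, marker, status) {
    sum(call_ihc_marker(df, marker) == status, na.rm = TRUE)
  }
  expect_equal(cnt(ma, "er", "negative"), 54)
  expect_equal(cnt(ma, "pr", "negative"), 56)
  expect_equal(sum(ma$her2_score == "3+"), 39)
  expect_equal(sum(ma$her2_score == "2+"), 5)
  expect_equal(sum(ma$her2_ish, na.rm = TRUE), 4)
  expect_equal(cnt(ma, "gcdfp15", "positive"), 33)
  expect_equal(cnt(ma, "ar", "positive"), 33)
  expect_equal(sum(!is.na(call_ihc_marker(ma, "ar"))), 57)
  expect_equal(cnt(ma, "foxa1", "positive"), 52)
  expect_equal(cnt(ma, "egfr", "negative"), 40)
  expect_equal(cnt(ma, "ck56", "negative"), 51)
  expect_equal(cnt(ma, "ck17", "negative"), 54)
  expect_equal(cnt(bl, "foxa1", "positive"), 4)
  expect_equal(cnt(bl, "egfr", "positive"), 9)
  expect_equal(cnt(bl, "ck56", "positive"), 8)
  expect_equal(cnt(bl, "ck17", "positive"), 8)
  expect_equal(sum(ma$tp53 == "nonfunctional"), 29)
  expect_equal(sum(ma$pik3ca != "wild_type"), 11)
  expect_equal(sum(ma$pik3ca == "H1047R"), 10)
  expect_true(all(bl$pik3ca == "wild_type"))
  # mRNA marginals: ERBB2 38 positive / 18 negative / 2 not determined
  expect_equal(sum(ma$ratio_ERBB2 > 7, na.rm = TRUE), 38)
  expect_equal(sum(is.na(ma$ratio_ERBB2)), 2)
  expect_equal(sum(bl$ratio_AR > 100), 2)
  # the ER(-) evaluation set has 67 tumors
  expect_equal(nrow(er_negative_subset(coh)), 67)
})
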