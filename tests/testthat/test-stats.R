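rec_row <- function(pid, group, idx, excluded = FALSE, Tm = 20) {
  data.frame(patient_id = pid, group = group, snapshot_index = idx,
             T_med_um = Tm, sigma_T_um = Tm / 2, C_s_per_mm = Tm / 10,
             n_holes = 3L, skeleton_length_um = 2000,
             excluded = excluded,
             exclusion_reason = if (excluded) "irregular" else "")
}

test_that("select_snapshots takes the first valid snapshot per patient", {
  rec <- rbind(rec_row("a", "Normal", 1), rec_row("a", "Normal", 2),
               rec_row("a", "Normal", 3),
               rec_row("b", "IPF", 1, excluded = TRUE),
               rec_row("b", "IPF", 2),
               rec_row("c", "HP", 1, excluded = TRUE),
               rec_row("c", "HP", 2, excluded = TRUE))
  sel <- select_snapshots(rec)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$snapshot_index[sel$patient_id == "a"], 1)
  expect_equal(sel$snapshot_index[sel$patient_id == "b"], 2)
  expect_equal(attr(sel, "dropped_patients"), "c")
})

test_that("wilcoxon exact p matches full enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_equal(w$method, "exact")
  expect_equal(w$p_value, oracle_wilcoxon_exact(1:3, 4:6))
  set.seed(50)
  for (k in 1:8) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  }
})

test_that("wilcoxon handles identical samples, symmetry, monotone maps", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  set.seed(51)
  x <- rnorm(15); y <- rnorm(12, 0.6)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_rank_sum(y, x)$p_value)
  expect_equal(wilcoxon_rank_sum(exp(x), exp(y))$p_value,
               wilcoxon_rank_sum(x, y)$p_value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact and approximate methods agree closely on tie-free n=6+6", {
  # exhaustive over every achievable statistic: the continuity-corrected
  # normal approximation deviates from the exact null by at most 0.0155
  # anywhere (most U values agree within 0.01; the worst case sits mid
  # distribution, far from any decision boundary near 0.05)
  diffs <- vapply(0:36, function(U) {
    x <- rep(0, 6); y <- rep(0, 6)
    # construct a tie-free sample achieving this U: interleave ranks
    ranks_x <- integer(0); u <- U
    for (k in 6:1) {
      take <- min(u, 6); ranks_x <- c(ranks_x, k + take); u <- u - take
    }
    vals <- seq_len(12)
    x <- vals[sort(ranks_x)]; y <- vals[-sort(ranks_x)]
    pe <- wilcoxon_rank_sum(x, y, exact = TRUE)$p_value
    pa <- wilcoxon_rank_sum(x, y, exact = FALSE)$p_value
    abs(pe - pa)
  }, numeric(1))
  expect_lt(max(diffs), 0.016)
  expect_lt(median(diffs), 0.01)
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.004, 12), 0.048)
  expect_equal(bonferroni(0.02, 12), 0.24)
  expect_equal(bonferroni(0.3, 12), 1.0)
  expect_error(bonferroni(0.5, 0), "m must be")
  expect_error(bonferroni(rep(0.01, 13), 12), "at least")
})

cohort_records <- function(groups, n = 8, shift = 1.5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(groups, function(g) {
    mult <- if (g == "Normal") 1 else shift
    data.frame(patient_id = paste0(g, seq_len(n)), group = g,
               snapshot_index = 1L,
               T_med_um = rnorm(n, 17, 1.5) * mult,
               sigma_T_um = rnorm(n, 9, 0.8) * mult,
               C_s_per_mm = rnorm(n, 1.7, 0.2) * mult,
               n_holes = 4L, skeleton_length_um = 2500,
               excluded = FALSE, exclusion_reason = "")
  }))
}

test_that("compare_groups produces the designed number of comparisons", {
  rec <- cohort_records(c("Normal", "COP", "HP", "NSIP", "IPF"))
  cmp <- compare_groups(rec)
  expect_equal(nrow(cmp), 12)
  expect_equal(attr(cmp, "m_tests"), 12)
  rec1 <- cohort_records(c("Normal", "IPF"))
  cmp1 <- compare_groups(rec1)
  expect_equal(nrow(cmp1), 3)
  expect_equal(attr(cmp1, "m_tests"), 3)
  expect_equal(cmp1$p_adjusted, pmin(1, cmp1$p_raw * 3))
  expect_error(compare_groups(cohort_records(c("COP", "IPF"))), "Normal")
  expect_error(compare_groups(cohort_records("Normal")), "pathology")
})

test_that("shifted pathology groups come out significant with positive delta", {
  hits <- 0
  for (s in 1:10) {
    rec <- cohort_records(c("Normal", "IPF"), n = 10, shift = 1.5, seed = s)
    cmp <- compare_groups(rec)
    if (all(cmp$delta > 0) && all(cmp$significant)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("render_report lays out Table-1 style rows with stars", {
  rec <- cohort_records(c("Normal", "COP", "HP", "NSIP", "IPF"), n = 10,
                        seed = 3)
  cmp <- compare_groups(rec)
  rep_ <- render_report(cmp)
  expect_equal(nrow(rep_), 5)
  expect_equal(rep_$group[1], "Normal")
  expect_equal(rep_$delta_T_med_um[1], "N/A")
  expect_equal(ncol(rep_), 7)     # group + 3 medians + 3 delta columns
  # star convention on adjusted p
  expect_equal(pcleQuant:::significance_stars(c(0.009, 0.03, 0.2)),
               c("**", "*", ""))
  stars_in_report <- grepl("\\*\\*", rep_$delta_T_med_um[-1])
  expect_equal(stars_in_report,
               cmp$p_adjusted[cmp$parameter == "T_med"] < 0.01)
  # csv writing round-trip
  f <- tempfile(fileext = ".csv")
  render_report(cmp, f)
  expect_equal(nrow(read.csv(f)), 5)
})

test_that("null simulation holds the nominal type-I error (quick check)", {
  set.seed(53)
  rej <- mean(replicate(2000,
    wilcoxon_rank_sum(rnorm(10), rnorm(10))$p_value < 0.05))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})
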