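test_that("uncorrected Pearson chi-squared reproduces the published p-values", {
  expect_equal(round(chisq_2x2(4, 78, 34, 179)$p.value, 4), 0.0109)
  expect_equal(round(chisq_2x2(33, 49, 50, 163)$p.value, 4), 0.0041)
  flat <- chisq_2x2(10, 10, 20, 20)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  expect_error(chisq_2x2(0, 0, 5, 5), "degenerate")
})

test_that("closed-form statistic equals the expected-count form and is symmetric", {
  set.seed(61)
  for (i in 1:50) {
    tab <- matrix(sample(1:80, 4, TRUE), 2)
    mine <- chisq_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-9)
    expect_equal(chisq_2x2(tab[2:1, ])$statistic, mine$statistic)
    expect_equal(chisq_2x2(tab[, 2:1])$statistic, mine$statistic)
  }
})

test_that("per-category comparison reproduces the published cohort contrasts", {
  icf2 <- cohort_table(c(4, 11, 34, 33), "ICF2")
  ctrl <- cohort_table(c(34, 52, 77, 50), "controls")
  cmp <- compare_categories(icf2, ctrl)
  expect_equal(round(cmp$p_value[cmp$class == "direct"], 4), 0.0109)
  expect_equal(round(cmp$p_value[cmp$class == "insertion"], 4), 0.0389)
  expect_equal(round(cmp$p_value[cmp$class == "mh_ge7"], 4), 0.0041)
  expect_equal(cmp$direction[cmp$class == "direct"], "down")
  expect_equal(cmp$direction[cmp$class == "mh_ge7"], "up")

  same <- compare_categories(icf2, icf2)
  expect_true(all(same$statistic == 0))

  # absent category in both cohorts (e.g. long microhomology at Smu-Sgamma)
  sg <- compare_categories(cohort_table(c(9, 3, 34, 0), "ICF2"),
                           cohort_table(c(13, 9, 36, 0), "controls"))
  expect_true(is.na(sg$p_value[sg$class == "mh_ge7"]))

  holm <- compare_categories(icf2, ctrl, adjust = "holm")
  expect_true(all(holm$p_adj >= holm$p_value, na.rm = TRUE))
})

test_that("Mann-Whitney U handles separation, identity and exact small samples", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  ident <- mann_whitney_u(c(1, 2, 5), c(1, 2, 5))
  expect_equal(ident$p.value, 1)

  # exact path agrees with wilcox.test for untied small samples
  set.seed(62)
  for (i in 1:20) {
    x <- sample(1:1000, sample(3:8, 1))
    y <- sample(1001:2000, sample(3:8, 1)) / 1.7
    mine <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney p equals full permutation enumeration", {
  perm_p <- function(x, y) {
    m <- length(x); N <- m + length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    labelings <- utils::combn(N, m)
    us <- apply(labelings, 2, function(idx)
      sum(r[idx]) - m * (m + 1) / 2)
    mn <- m * (N - m)
    p1 <- if (obs > mn / 2) mean(us >= obs) else mean(us <= obs)
    min(1, 2 * p1)
  }
  cases <- list(list(c(1, 3, 5), c(2, 4)),
                list(c(10, 12, 14, 16), c(11, 13, 15)),
                list(c(1, 2), c(3, 4, 5, 6)))
  for (cs in cases) {
    mine <- mann_whitney_u(cs[[1]], cs[[2]])
    expect_equal(mine$p.value, perm_p(cs[[1]], cs[[2]]), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("plasmid-integration efficiency follows the printed formula", {
  expect_equal(plasmid_integration_efficiency(0.2, 0.5, 0.8,
                                              control = c(0.2, 0.5, 0.8)), 1)
  expect_equal(plasmid_integration_efficiency(0.05, 0.5, 0.8,
                                              control = 0.25), 0.5)
  base <- plasmid_integration_efficiency(0.05, 0.5, 0.4)
  expect_equal(plasmid_integration_efficiency(0.05, 0.5, 0.8), base / 2)
  expect_error(plasmid_integration_efficiency(0, 0.5, 0.8), "in \\(0, 1\\]")
})

test_that("relative accumulation is expressed relative to the nucleoplasm", {
  expect_equal(relative_accumulation(100, 100, 50), 0)
  expect_equal(relative_accumulation(200, 100, 50), 2)
  expect_equal(relative_accumulation(50, 100, 50), -1)
  expect_error(relative_accumulation(100, 50, 50), "nucleoplasm")
})

test_that("tidy and glance return one-row summaries for test objects", {
  t <- chisq_2x2(4, 78, 34, 179)
  td <- tidy(t)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("statistic", "df", "p.value", "method"))
  gl <- glance(t)
  expect_equal(gl$n, 295L)
  cmp <- compare_categories(cohort_table(c(4, 11, 34, 33), "a"),
                            cohort_table(c(34, 52, 77, 50), "b"))
  g2 <- glance(cmp)
  expect_equal(g2$n_categories, 4L)
  expect_equal(g2$total_a, 82L)
})
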