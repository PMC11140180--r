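test_that("two-condition repeated-measures F equals the paired t squared", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    d <- data.frame(animal_id = rep(sprintf("a%d", 1:n), each = 2),
                    state = rep(c("s1", "s2"), n),
                    y = stats::rnorm(2 * n, mean = rep(c(0, 0.5), n)))
    an <- rm_anova(d, "y")
    tt <- paired_t(d$y[d$state == "s1"], d$y[d$state == "s2"])
    expect_equal(an$F, tt$t^2, tolerance = 1e-10)
    expect_equal(an$p, tt$p, tolerance = 1e-10)
  }
})

test_that("rm_anova matches the aov() decomposition on a fixture", {
  d <- fix_rm_table()
  mine <- rm_anova(d, "y")
  ref <- summary(stats::aov(y ~ state + Error(animal_id), data = d))
  tab <- ref[["Error: Within"]][[1]]
  expect_equal(mine$F, tab[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p, tab[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(mine$SS_condition, tab[["Sum Sq"]][1], tolerance = 1e-10)
  expect_equal(mine$SS_error, tab[["Sum Sq"]][2], tolerance = 1e-10)
  expect_equal(mine$df1, 2L)
  expect_equal(mine$df2, 6L)
})

test_that("rm_anova is invariant to per-animal constants", {
  d <- fix_rm_table()
  f0 <- rm_anova(d, "y")$F
  d$y <- d$y + rep(c(100, -40, 7, 0.5), each = 3)
  expect_equal(rm_anova(d, "y")$F, f0, tolerance = 1e-10)
})

test_that("identical values give the degenerate zero-error flag", {
  d <- fix_rm_table(); d$y <- 5
  an <- rm_anova(d, "y")
  expect_true(an$degenerate)
})

test_that("animals missing a state are dropped with a warning", {
  d <- fix_rm_table()[-2, ]   # a1 loses TAD1
  expect_warning(an <- rm_anova(d, "y"), "dropping 1")
  expect_equal(an$n, 3)
})

test_that("Bonferroni adjustment caps at one and never lowers p", {
  d <- fix_rm_table()
  pw <- bonferroni_pairwise(d, "y")
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adj >= pw$p))
  expect_true(all(pw$p_adj <= 1))
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p), tolerance = 1e-12)
  # property across random tables
  set.seed(14)
  for (i in 1:10) {
    d$y <- stats::rnorm(12)
    pw <- bonferroni_pairwise(d, "y")
    expect_true(all(pw$p_adj >= pw$p - 1e-15 & pw$p_adj <= 1))
  }
})

test_that("paired_t handles degenerate differences as flagged cases", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  r <- paired_t(x, x)
  expect_true(r$degenerate)
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  r2 <- paired_t(x + 2, x)
  expect_true(r2$degenerate)
  expect_true(is.infinite(r2$t) && r2$t > 0)
  # hand formula on six pairs
  set.seed(3)
  a <- stats::rnorm(6); b <- stats::rnorm(6)
  r3 <- paired_t(a, b)
  dd <- a - b
  expect_equal(r3$t, mean(dd) / (stats::sd(dd) / sqrt(6)),
               tolerance = 1e-12)
  expect_equal(r3$df, 5)
})

test_that("compact letters separate exactly the significant pairs", {
  states <- c("basal", "TAD1", "TAD2")
  pw <- data.frame(state_a = c("basal", "basal", "TAD1"),
                   state_b = c("TAD1", "TAD2", "TAD2"),
                   p_adj = c(0.9, 0.01, 0.02))
  lt <- compact_letters(pw, states)
  expect_equal(unname(lt["basal"]), unname(lt["TAD1"]))
  expect_false(any(strsplit(lt[["TAD2"]], "")[[1]] %in%
                     strsplit(lt[["basal"]], "")[[1]]))
  # nothing significant -> one shared letter
  pw$p_adj <- c(0.5, 0.7, 0.9)
  expect_equal(unique(unname(compact_letters(pw, states))), "a")
  # everything different -> three distinct letters
  pw$p_adj <- c(0.01, 0.01, 0.01)
  expect_equal(length(unique(compact_letters(pw, states))), 3)
})

test_that("summary table carries means, SDs, letters and ANOVA columns", {
  d <- fix_rm_table()
  s <- summarize_cohort(d, "y", states = c("basal", "TAD1", "TAD2"))
  expect_equal(nrow(s), 1)
  expect_true(all(c("variable", "F", "df1", "df2", "p",
                    "mean_basal", "sd_basal", "letters_basal",
                    "mean_TAD1", "mean_TAD2") %in% names(s)))
  expect_equal(s$mean_basal, mean(d$y[d$state == "basal"]))
})

test_that("time series binning averages fixed-width windows", {
  b <- bin_time_average(c(0, 1, 4, 5, 6, 11), c(2, 4, 6, 1, 3, 9), width = 5)
  expect_equal(b$bin_start, c(0, 5, 10))
  expect_equal(b$mean, c(4, 2, 9))
})
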