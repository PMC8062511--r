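test_that("factorial design validates its factors", {
  fd <- factorial_design()
  expect_identical(length(fd$designs) * length(fd$diameters) *
                     length(fd$plaque_modes) * length(fd$seeds), 288L)
  expect_error(factorial_design(designs = "WALLSTENT"), "unknown design")
  expect_error(factorial_design(plaque_modes = "adamantium"),
               "unknown plaque mode")
  expect_error(factorial_design(seeds = integer(0)))
})

test_that("a 1x1x1x1 factorial yields exactly one complete row", {
  fd <- factorial_design(designs = "MEGATRON_9", diameters = 4.5,
                         plaque_modes = "neutral", seeds = 1)
  tab <- run_factorial(fd)
  expect_identical(nrow(tab), 1L)
  expect_identical(attr(tab, "attempted"), 1L)
  expect_identical(attr(tab, "completed"), 1L)
  expect_identical(nrow(attr(tab, "failures")), 0L)
  expect_identical(tab$design, "MEGATRON_9")
  expect_identical(tab$plaque, "neutral")
  expect_false(is.na(tab$hoop_force))
})

test_that("reruns with identical seeds are byte-identical on disk", {
  fd <- factorial_design(designs = "SYNERGY", diameters = 3.5,
                         plaque_modes = "soft", seeds = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(run_factorial(fd), f1)
  write_results_csv(run_factorial(fd), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("expansion difference reproduces the percentage formula by hand", {
  tab <- tibble::tibble(
    design = rep(c("MEGATRON_12", "MEGATRON_9"), each = 3),
    diameter = 4.5, plaque = "neutral", seed = rep(1:3, 2),
    msd = c(4.2, 4.2, 4.2, 4.0, 4.0, 4.0)
  )
  out <- expansion_difference(tab, "MEGATRON_12", "MEGATRON_9")
  expect_identical(nrow(out), 1L)
  # (4.2 - 4.0) / 4.0 * 100 = 5.0 %
  expect_equal(out$mean_pct_diff, 5.0)
  expect_equal(out$sem_pct_diff, 0)  # constant per-seed differences
  expect_identical(out$n_seeds, 3L)
  # identical MSDs -> 0 %
  tab0 <- dplyr::mutate(tab, msd = 4.1)
  expect_equal(
    expansion_difference(tab0, "MEGATRON_12", "MEGATRON_9")$mean_pct_diff, 0)
  # a missing block is an error that names the absent combination
  expect_error(expansion_difference(tab[-1, ], "MEGATRON_12", "MEGATRON_9"),
               "seed 1")
  expect_error(expansion_difference(tab, "MEGATRON_12", "ABSENT"),
               "not in table")
})

test_that("identical groups give adjusted p = 1 in both branches", {
  tab <- tibble::tibble(
    design = rep(c("A", "B", "C"), each = 4),
    seed = rep(1:4, 3),
    msd = 4.0
  )
  cmp <- compare_groups(tab, "msd")
  expect_s3_class(cmp, "group_comparison")
  expect_true(all(cmp$anova$pairwise$p_adjusted == 1))
  expect_true(all(cmp$friedman$pairwise$p_adjusted == 1))
  expect_equal(cmp$anova$p_value, 1)
})

test_that("a large injected shift is detected below 0.05 adjusted", {
  set.seed(31)
  tab <- tibble::tibble(
    design = rep(c("A", "B", "C"), each = 20),
    seed = rep(1:20, 3),
    msd = stats::rnorm(60, mean = 4, sd = 0.02) +
      rep(c(0, 0, 0.5), each = 20)
  )
  cmp <- compare_groups(tab, "msd")
  pw <- cmp$anova$pairwise
  expect_lt(pw$p_adjusted[pw$group1 == "A" & pw$group2 == "C"], 0.05)
  expect_lt(pw$p_adjusted[pw$group1 == "B" & pw$group2 == "C"], 0.05)
  expect_gt(pw$p_adjusted[pw$group1 == "A" & pw$group2 == "B"], 0.05)
  dn <- cmp$friedman$pairwise
  expect_lt(dn$p_adjusted[dn$group1 == "A" & dn$group2 == "C"], 0.05)
})

test_that("the Friedman statistic matches the textbook rank formula by hand", {
  # 4 blocks x 3 groups, no ties
  mat <- rbind(c(1.0, 2.0, 3.0),
               c(2.1, 1.1, 3.1),
               c(1.2, 2.2, 3.2),
               c(1.3, 2.3, 3.3))
  colnames(mat) <- c("A", "B", "C")
  tab <- tibble::tibble(
    design = rep(colnames(mat), each = 4),
    seed = rep(1:4, 3),
    msd = c(mat[, 1], mat[, 2], mat[, 3])
  )
  cmp <- compare_groups(tab, "msd")
  n <- 4; k <- 3
  rsum <- colSums(t(apply(mat, 1, rank)))   # A: 5, B: 7, C: 12
  chi2 <- 12 / (n * k * (k + 1)) * sum(rsum^2) - 3 * n * (k + 1)
  expect_equal(cmp$friedman$statistic, chi2)
  # Dunn z for a pair: |R_i - R_j| / sqrt(n k (k+1) / 6)
  dn <- cmp$friedman$pairwise
  z_ac <- abs(rsum["A"] - rsum["C"]) / sqrt(n * k * (k + 1) / 6)
  expect_equal(unname(dn$z[dn$group1 == "A" & dn$group2 == "C"]),
               unname(z_ac))
  expect_equal(dn$p_adjusted,
               pmin(2 * stats::pnorm(-dn$z) * nrow(dn), 1))
})

test_that("compare_groups enforces its preconditions", {
  one <- tibble::tibble(design = rep("A", 4), seed = 1:4, msd = rnorm(4))
  expect_error(compare_groups(one, "msd"), "2 groups")
  tiny <- tibble::tibble(design = rep(c("A", "B"), each = 2),
                         seed = rep(1:2, 2), msd = rnorm(4))
  expect_error(compare_groups(tiny, "msd"), "3 observations")
})

test_that("make_report writes deterministic grouped summaries", {
  tab <- tibble::tibble(
    design = rep(c("MEGATRON_9", "SYNERGY"), each = 4),
    diameter = 4.5, plaque = rep(c("soft", "stiff"), 4),
    seed = rep(1:2, 4),
    msd = c(4.1, 4.0, 4.2, 4.1, 3.9, 3.8, 4.0, 3.9),
    ccd = 1.1, prolapse = 0.08, sar = 13, hoop_force = 0.07,
    radial_strength = 0.02
  )
  dir1 <- withr::local_tempdir()
  s <- make_report(tab, dir1)
  expect_identical(nrow(s$msd), 4L)  # 2 designs x 1 diameter x 2 plaques
  expect_true(file.exists(file.path(dir1, "msd_summary.csv")))
  dir2 <- withr::local_tempdir()
  make_report(tab, dir2)
  p1 <- file.path(dir1, "sar_summary.csv")
  p2 <- file.path(dir2, "sar_summary.csv")
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # empty subset: well-formed empty summaries
  s0 <- make_report(tab[0, ], out_dir = NULL)
  expect_identical(nrow(s0$msd), 0L)
  expect_true(all(c("design", "diameter", "plaque", "mean", "sem", "n") %in%
                    names(s0$msd)))
})
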