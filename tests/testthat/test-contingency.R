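test_that("Pearson statistic matches the printed decision-table values", {
  # plus-one perturbations of the 87/1687 two-feature table
  expect_equal(chi2_stat(rbind(c(38, 12, 26, 12), c(184, 1026, 289, 188))),
               109.2, tolerance = 0.05 / 109.2)
  expect_equal(chi2_stat(rbind(c(38, 12, 26, 11), c(184, 1026, 289, 189))),
               110.1, tolerance = 0.05 / 110.1)
  # reweighted (balanced) forms pin down "no continuity correction"
  th <- 87 / 1687
  expect_equal(chi2_stat(rbind(c(38, 12, 26, 12),
                               c(184, 1026, 289, 188) * th)),
               46.2, tolerance = 0.05 / 46.2)
  neg <- c(184, 1026, 289, 188) * th
  neg[4] <- neg[4] + 1
  expect_equal(chi2_stat(rbind(c(38, 12, 26, 11), neg)),
               45.9, tolerance = 0.05 / 45.9)
})

test_that("statistic is zero iff rows are proportional, errors when empty", {
  expect_equal(chi2_stat(rbind(c(5, 10, 15), c(10, 20, 30))), 0)
  expect_error(chi2_stat(rbind(c(0, 0), c(0, 0))), "degenerate")
  withr::with_seed(42, {
    for (i in 1:50) {
      m <- matrix(rpois(8, 20) + 1, nrow = 2)
      expect_equal(chi2_stat(m), oracle_chi2(m), tolerance = 1e-10)
      expect_gt(chi2_stat(m + 0), -1e-12)
      prop <- rbind(m[1, ], m[1, ] * runif(1, 0.1, 5))
      expect_equal(chi2_stat(prop), 0, tolerance = 1e-8)
    }
  })
})

test_that("upper-tail p-values hit the classic critical points", {
  expect_equal(chi2_pvalue(0, 1), 1)
  expect_equal(chi2_pvalue(3.841, 1), 0.05, tolerance = 1e-3)
  expect_equal(chi2_pvalue(6.635, 1), 0.01, tolerance = 1e-3)
  expect_error(chi2_pvalue(1, 0), "df")
  # monotone decreasing, and log form does not underflow
  expect_true(all(diff(chi2_pvalue(seq(0, 50, 5), 3)) < 0))
  expect_lt(chi2_pvalue(4000, 1, log10p = TRUE), -800)
})

test_that("local merge test treats empty columns as freely mergeable", {
  expect_equal(local_merge_test(c(10, 100), c(10, 100)), 1)
  expect_equal(local_merge_test(c(0, 0), c(7, 3)), 1)
  expect_lt(local_merge_test(c(38, 184), c(12, 1026)), 1e-10)
  expect_equal(local_merge_test(c(3, 30), c(4, 40)),
               oracle_p_2x2(cbind(c(3, 30), c(4, 40))), tolerance = 1e-12)
})

test_that("compression merges class-indistinguishable columns and stops", {
  # indistinguishable pair collapses fully
  res <- compress_table(chi_table(c(10, 10), c(10, 10)))
  expect_equal(length(res$table$groups), 1)
  # A/T and C/G rowwise proportional; the AT-vs-CG contrast survives
  t4 <- chi_table(c(30, 100, 120, 31), c(300, 400, 480, 298),
                  groups = list("A", "C", "G", "T"))
  res <- compress_table(t4, alpha = 0.01)
  got <- lapply(res$table$groups, sort)
  expect_equal(got[order(vapply(got, `[`, character(1), 1))],
               list(c("A", "T"), c("C", "G")))
  expect_false(res$decisions$accepted[nrow(res$decisions)])
})

test_that("compression equals the explicit merge-sequence oracle", {
  withr::with_seed(7, {
    for (i in 1:200) {
      r <- sample(2:5, 1)
      ordinal <- runif(1) < 0.5
      m <- matrix(rpois(2 * r, sample(c(3, 25), 1)), nrow = 2)
      if (runif(1) < 0.2) m[, sample(r, 1)] <- 0  # unseen status column
      tab <- chi_table(m[1, ], m[2, ],
                       groups = as.list(as.character(seq_len(r))),
                       ordinal = ordinal)
      mine <- compress_table(tab, alpha = 0.01)$table
      orc <- oracle_compress(m, ordinal, alpha = 0.01)
      expect_equal(unname(mine$counts), unname(orc$counts),
                   tolerance = 1e-9)
      expect_equal(lapply(mine$groups, as.integer), orc$groups)
      # groups partition the original domain
      expect_setequal(unlist(mine$groups), as.character(seq_len(r)))
      # ordinal groups are contiguous runs
      if (ordinal) {
        for (g in mine$groups) {
          idx <- sort(as.integer(g))
          expect_equal(idx, seq(min(idx), max(idx)))
        }
      }
      # idempotence
      again <- compress_table(mine, alpha = 0.01)$table
      expect_equal(again$counts, mine$counts)
    }
  })
})

test_that("grid mutual information reproduces the printed 2x3 grid value", {
  g <- grid_mutual_information(rbind(c(0, 4, 6), c(2, 0, 8)))
  expect_equal(g$normalized, 0.31, tolerance = 0.005 / 0.31)
  expect_equal(grid_mutual_information(rbind(c(5, 5), c(5, 5)))$mi_bits, 0)
  expect_equal(grid_mutual_information(rbind(c(10, 0), c(0, 10)))$normalized, 1)
  expect_error(grid_mutual_information(rbind(c(0, 0), c(0, 0))), "degenerate")
})

test_that("grid MI is invariant to permutation and scaling", {
  withr::with_seed(11, {
    for (i in 1:20) {
      m <- matrix(rpois(6, 10), nrow = 2)
      if (sum(m) == 0) next
      base <- grid_mutual_information(m)$mi_bits
      expect_equal(grid_mutual_information(m[2:1, ])$mi_bits, base)
      expect_equal(grid_mutual_information(m[, sample(3)])$mi_bits, base)
      expect_equal(grid_mutual_information(m * 3.7)$mi_bits, base)
    }
  })
})

test_that("tables round-trip through the TSV representation", {
  tab <- chi_table(c(5, 7), c(2.5, 1.25),
                   groups = list(c("A", "T"), c("C", "G")))
  path <- withr::local_tempfile()
  write_chi_table(tab, path)
  back <- read_chi_table(path)
  expect_equal(unname(back$counts), unname(tab$counts))
  expect_equal(back$groups, tab$groups)
})
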