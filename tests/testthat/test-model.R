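test_that("entropy, gain and gain ratio follow the direct formulas", {
  expect_equal(entropy(50, 50), 1)
  expect_equal(entropy(100, 0), 0)
  expect_equal(entropy(87, 1687), oracle_entropy(87, 1687))
  expect_equal(entropy(87, 1687), 0.28231, tolerance = 1e-4)
  expect_error(entropy(0, 0), "degenerate")

  parent <- tibble::tibble(cell = 1L, pos = 50, neg = 50)
  indep <- tibble::tibble(cell = 1L, sub = 1:2, pos = c(25, 25),
                          neg = c(25, 25))
  expect_equal(information_gain(parent, indep), 0)
  perfect <- tibble::tibble(cell = 1L, sub = 1:2, pos = c(50, 0),
                            neg = c(0, 50))
  expect_equal(information_gain(parent, perfect), 1)
  expect_error(information_gain(parent,
    tibble::tibble(cell = 1L, sub = 1:2, pos = c(30, 25), neg = c(25, 25))),
    "partition")

  # the 87/1687 set split along the printed four rules
  p14 <- tibble::tibble(cell = 1L, pos = 87, neg = 1687)
  c14 <- tibble::tibble(cell = 1L, sub = 1:4, pos = c(38, 12, 26, 11),
                        neg = c(184, 1026, 289, 188))
  gain_expected <- oracle_entropy(87, 1687) -
    sum((c14$pos + c14$neg) / 1774 * mapply(oracle_entropy, c14$pos, c14$neg))
  expect_equal(information_gain(p14, c14), gain_expected)
  sizes <- c14$pos + c14$neg  # 222, 1038, 315, 199
  iv_expected <- -sum(sizes / 1774 * log2(sizes / 1774))
  expect_equal(gain_ratio(information_gain(p14, c14), sizes),
               gain_expected / iv_expected)

  expect_equal(gain_ratio(1, c(8, 8)), 1)
  expect_equal(gain_ratio(1, c(5, 5, 5, 5)), 0.5)  # uniform 4-way IV = 2
  expect_error(gain_ratio(0.5, c(10, 0)), "intrinsic")
})

test_that("gain is non-negative and bounded by parent entropy", {
  withr::with_seed(13, {
    for (i in 1:30) {
      pos <- rpois(3, 20); neg <- rpois(3, 20)
      if (sum(pos) + sum(neg) == 0 || any(pos + neg == 0)) next
      parent <- tibble::tibble(cell = 1L, pos = sum(pos), neg = sum(neg))
      children <- tibble::tibble(cell = 1L, sub = 1:3, pos = pos, neg = neg)
      g <- information_gain(parent, children)
      expect_gte(g, -1e-12)
      expect_lte(g, entropy(sum(pos), sum(neg)) + 1e-12)
    }
  })
})

test_that("feature introduction handles the degenerate extremes", {
  # one perfectly separating binary feature
  enc <- tibble::tibble(
    label = rep(c("positive", "negative"), each = 30),
    F1 = rep(c("X", "Y"), each = 30),
    F2 = rep(c("X", "Y"), 30))
  specs <- tibble::tibble(id = c("F1", "F2"), kind = "categorical",
                          domain = list(c("X", "Y"), c("X", "Y")))
  got <- introduce_features(enc, specs)
  expect_equal(got$features, "F1")
  expect_equal(nrow(got$rules), 2)
  expect_equal(sort(got$rules$pos), c(0, 30))
  # all features class-independent: nothing introduced
  enc2 <- enc
  enc2$F1 <- rep(c("X", "Y"), 30)
  got2 <- introduce_features(enc2, specs)
  expect_equal(got2$features, character(0))
  expect_equal(nrow(got2$rules), 1)
})

test_that("feature introduction matches the plain-loop oracle", {
  specs <- tibble::tibble(
    id = c("F1", "F2", "F3"),
    kind = c("categorical", "categorical", "ordinal"),
    domain = list(c("A", "C", "G", "T"), c("X", "Y"),
                  as.character(0:3)))
  withr::with_seed(17, {
    for (rep in 1:15) {
      n <- 80
      df <- tibble::tibble(
        label = sample(c("positive", "negative"), n, TRUE, prob = c(.4, .6)),
        F1 = sample(c("A", "C", "G", "T"), n, TRUE,
                    prob = c(.4, .3, .2, .1)),
        F2 = sample(c("X", "Y"), n, TRUE),
        F3 = as.character(sample(0:3, n, TRUE)))
      # plant structure: positives lean on F1 = A and high F3
      flip <- df$label == "positive" & runif(n) < 0.6
      df$F1[flip] <- "A"
      df$F3[df$label == "positive" & runif(n) < 0.5] <- "3"
      if (length(unique(df$label)) < 2) next
      mine <- introduce_features(df, specs, alpha = 0.05)
      orc <- oracle_introduce(as.data.frame(df), specs, alpha = 0.05)
      expect_equal(mine$features, orc$features)
      expect_equal(cbind(mine$rules$pos, mine$rules$neg),
                   unname(orc$cell_counts))
    }
  })
})

test_that("theta reweighting reproduces the printed balanced tables", {
  th <- 2000 / 271132
  expect_equal(round(47512 * th, 1), 350.5)
  part <- tibble::tibble(
    rule = 1:2, conditions = list(list(), list()),
    pos = c(5, 11), neg = c(47512, 368))
  d <- build_decision_table(part, theta = th)
  expect_equal(round(d$neg_weighted, 1), c(350.5, 2.7))

  fx <- worked_fixtures()
  part14 <- tibble::tibble(rule = 1:4,
                           conditions = replicate(4, list(), simplify = FALSE),
                           pos = fx$table_imbalanced[1, ],
                           neg = fx$table_imbalanced[2, ])
  bal <- build_decision_table(part14, balanced = TRUE)
  expect_equal(round(unname(bal$neg_weighted), 1), c(9.5, 52.9, 14.9, 9.7))
  # balanced table equalizes total class mass
  expect_equal(sum(bal$neg_weighted), sum(bal$pos))
  # theta = 1 reproduces the raw table
  raw <- build_decision_table(part14, balanced = FALSE)
  expect_equal(raw$neg_weighted, raw$neg)
  expect_error(build_decision_table(
    dplyr::mutate(part14, neg = 0), balanced = TRUE), "balance")
})

test_that("the plus-one rule reproduces the narrated worked decision", {
  fx <- worked_fixtures()
  part <- tibble::tibble(
    rule = 1:4,
    conditions = list(list(`P-1` = c("A", "C", "T"), `P+3` = c("A", "T")),
                      list(`P-1` = c("A", "C", "T"), `P+3` = c("G", "C")),
                      list(`P-1` = "G", `P+3` = c("A", "T")),
                      list(`P-1` = "G", `P+3` = c("G", "C"))),
    pos = fx$table_imbalanced[1, ], neg = fx$table_imbalanced[2, ])
  sample4 <- tibble::tibble(`P-1` = "G", `P+3` = "G")
  imb <- classify_samples(sample4, build_decision_table(part, balanced = FALSE))
  expect_equal(imb$chi2_pos, 109.2, tolerance = 0.05 / 109.2)
  expect_equal(imb$chi2_neg, 110.1, tolerance = 0.05 / 110.1)
  expect_equal(imb$label, "negative")
  bal <- classify_samples(sample4, build_decision_table(part, balanced = TRUE))
  expect_equal(bal$chi2_pos, 46.2, tolerance = 0.05 / 46.2)
  expect_equal(bal$chi2_neg, 45.9, tolerance = 0.05 / 45.9)
  expect_equal(bal$label, "positive")
  expect_equal(bal$score, bal$chi2_pos - bal$chi2_neg)
})

test_that("a single-rule table ties and predicts negative", {
  part <- tibble::tibble(rule = 1L, conditions = list(list()),
                         pos = 10, neg = 20)
  got <- classify_samples(tibble::tibble(x = 1),
                          build_decision_table(part))
  expect_equal(got$chi2_pos, got$chi2_neg)
  expect_equal(got$label, "negative")
})

test_that("every possible window matches exactly one fitted rule", {
  sim <- simulate_donor_data(80, 400, seed = 3)
  sim$window <- extract_window(sim$seq)
  fit <- chidt_fit(sim)
  w <- withr::with_seed(23, random_window(10000))
  preds <- predict(fit, tibble::tibble(window = w))
  expect_equal(nrow(preds), 10000)  # errors if any window matched 0 or 2 rules
  expect_true(all(preds$label %in% c("positive", "negative")))
  expect_true(all((preds$score > 0) == (preds$label == "positive") |
                    preds$score <= 0))
})

test_that("fitting is deterministic and predictions are self-consistent", {
  sim <- simulate_donor_data(60, 300, seed = 5)
  sim$window <- extract_window(sim$seq)
  f1 <- chidt_fit(sim)
  f2 <- chidt_fit(sim)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_chidt_model(f1, p1); write_chidt_model(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a duplicated training positive classifies like its own vector
  w <- sim$window[sim$label == "positive"][1]
  batch <- predict(f1, tibble::tibble(window = c(w, w)))
  single <- classify_samples(encode_windows(tibble::tibble(window = w),
                                            specs = f1$specs), f1$dtable)
  expect_equal(batch$label[1], single$label)
  expect_equal(batch$score, rep(single$score, 2))
})

test_that("models survive a save/load round trip bit-exactly", {
  sim <- simulate_donor_data(50, 200, seed = 8)
  sim$window <- extract_window(sim$seq)
  fit <- chidt_fit(sim)
  path <- withr::local_tempfile()
  write_chidt_model(fit, path)
  back <- read_chidt_model(path)
  expect_identical(back$features, fit$features)
  expect_identical(back$dtable$pos, fit$dtable$pos)
  expect_identical(back$dtable$neg, fit$dtable$neg)
  expect_identical(back$dtable$neg_weighted, fit$dtable$neg_weighted)
  expect_identical(attr(back$dtable, "theta"), attr(fit$dtable, "theta"))
  expect_identical(back$dtable$conditions, fit$dtable$conditions)
  w <- withr::with_seed(31, random_window(200))
  expect_identical(predict(back, tibble::tibble(window = w)),
                   predict(fit, tibble::tibble(window = w)))
})

test_that("tidy and glance summarize the fitted table", {
  sim <- simulate_donor_data(40, 160, seed = 12)
  sim$window <- extract_window(sim$seq)
  fit <- chidt_fit(sim)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(fit$dtable))
  expect_true(all(grepl("=", td$conditions)))
  gl <- glance(fit)
  expect_equal(gl$n_pos, 40)
  expect_equal(gl$theta, 40 / 160)
  expect_true(gl$balanced)
})
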