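test_that("split-plot ANOVA reproduces a hand-computed 2x3 example", {
  ## two groups of three subjects, three repeated levels; all sums of
  ## squares worked out by hand on the cell/subject/level means:
  ## SS_group = 128/9, SS_subjects(group) = 130/9, SS_level = 100/3,
  ## SS_interaction = 28/9, SS_error = 8/9, SS_total = 66.
  vals <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 6),
                c(2, 4, 6), c(2, 5, 7), c(4, 6, 8))
  tab <- long_table(vals, rep(c("g1", "g2"), each = 3))
  an <- split_plot_anova(tab, "m")
  e <- an$effects
  expect_equal(e$SS[e$effect == "group"], 128 / 9)
  expect_equal(an$ss_subjects, 130 / 9)
  expect_equal(e$SS[e$effect == "fap"], 100 / 3)
  expect_equal(e$SS[e$effect == "group:fap"], 28 / 9)
  expect_equal(an$ss_error, 8 / 9)
  expect_equal(an$ss_total, 66)
  expect_equal(e$df1, c(1, 2, 2))
  expect_equal(e$df2, c(4, 8, 8))
  expect_equal(e$F[e$effect == "group"], (128 / 9) / (65 / 18))
  expect_equal(e$F[e$effect == "fap"], 150)
  expect_equal(e$F[e$effect == "group:fap"], 14)
})

test_that("ANOVA agrees with the stratified aov cross-check", {
  set.seed(23)
  vals <- matrix(rnorm(36), 12, 3) + outer(rnorm(12), c(0, 1, 3))
  tab <- long_table(vals, rep(c("a", "b"), each = 6))
  an <- split_plot_anova(tab, "m")
  tab$fap_level <- factor(tab$fap_level)
  fit <- summary(stats::aov(value ~ group * fap_level +
                              Error(specimen_id / fap_level), data = tab))
  between <- fit[["Error: specimen_id"]][[1]]
  within <- fit[["Error: specimen_id:fap_level"]][[1]]
  e <- an$effects
  expect_equal(e$F[e$effect == "group"], between["group", "F value"],
               tolerance = 1e-10)
  expect_equal(e$F[e$effect == "fap"], within["fap_level", "F value"],
               tolerance = 1e-10)
  expect_equal(e$p[e$effect == "group:fap"],
               within["group:fap_level", "Pr(>F)"], tolerance = 1e-10)
})

test_that("degenerate and unbalanced tables are rejected or flat", {
  vals <- matrix(5, 4, 3)
  tab <- long_table(vals, rep(c("a", "b"), each = 2))
  an <- split_plot_anova(tab, "m")
  expect_equal(an$effects$F, c(0, 0, 0))
  expect_equal(an$effects$p, c(1, 1, 1))
  expect_error(split_plot_anova(tab[-1, ], "m"), "unbalanced")
  expect_error(split_plot_anova(tab, "nope"), "not found")
})

test_that("studentized range quadrature matches an independent oracle", {
  for (k in c(2, 3, 5)) for (df in c(5, 12, 60)) {
    expect_equal(ptukey_range(3.1, k, df), stats::ptukey(3.1, k, df),
                 tolerance = 1e-6)
  }
  expect_equal(qtukey_range(0.95, 3, 10), stats::qtukey(0.95, 3, 10),
               tolerance = 1e-4)
  expect_equal(qtukey_range(0.95, 2, 8), stats::qtukey(0.95, 2, 8),
               tolerance = 1e-4)
  ## df = Inf reduces to the range of standard normals
  expect_equal(ptukey_range(3.3, 4, Inf), stats::ptukey(3.3, 4, Inf),
               tolerance = 1e-7)
})

test_that("SNK reproduces a hand-worked three-mean example", {
  ## means 10, 12, 18; MSE = 4, df = 12, n = 4 => SE = 1.
  ## span 3: q = 8 > q_crit(3,12) = 3.77 -> significant
  ## span 2 (12 vs 18): q = 6 > q_crit(2,12) = 3.08 -> significant
  ## span 2 (10 vs 12): q = 2 < 3.08 -> not significant
  res <- snk_posthoc(c(lo = 10, mid = 12, hi = 18), error_ms = 4,
                     error_df = 12, n_per_mean = 4)
  p <- res$pairs
  expect_true(p$significant[p$lower == "lo" & p$upper == "hi"])
  expect_true(p$significant[p$lower == "mid" & p$upper == "hi"])
  expect_false(p$significant[p$lower == "lo" & p$upper == "mid"])
  expect_equal(res$subsets, list(c("lo", "mid"), "hi"))
  expect_equal(p$q[p$lower == "lo" & p$upper == "hi"], 8)
})

test_that("SNK protection makes inner pairs of a homogeneous range ns", {
  ## overall range below its critical value: everything one subset
  res <- snk_posthoc(c(a = 10, b = 10.5, c = 11), error_ms = 4,
                     error_df = 12, n_per_mean = 4)
  expect_false(any(res$pairs$significant))
  expect_equal(res$subsets, list(c("a", "b", "c")))
  ## subsets are always intervals in the ordered means
  set.seed(29)
  for (i in 1:20) {
    m <- rnorm(5, sd = 3)
    names(m) <- letters[1:5]
    res <- snk_posthoc(m, 1, 10, 3)
    ord <- names(res$ordered_means)
    for (ss in res$subsets) {
      pos <- match(ss, ord)
      expect_equal(pos, seq(min(pos), max(pos)))
    }
  }
  expect_error(snk_posthoc(c(1, 2), -1, 10, 3), "error_ms")
})

test_that("cohort summaries give t-based confidence half-widths", {
  tab <- data.frame(specimen_id = sprintf("s%d", 1:6), group = "g",
                    fap_level = 0, metric = "m", value = 1:6)
  sm <- summarize_cohort(tab)
  expect_equal(sm$mean, 3.5)
  expect_equal(sm$ci_halfwidth,
               stats::qt(0.975, 5) * stats::sd(1:6) / sqrt(6),
               tolerance = 1e-12)
  expect_equal(round(sm$ci_halfwidth, 3), 1.963)
  tab1 <- tab[1, ]
  expect_error(summarize_cohort(tab1), "fewer than 2")
})

test_that("simple effects compare levels within group and groups per level", {
  set.seed(37)
  vals <- rbind(matrix(rnorm(18, 10), 6, 3) %*% diag(c(1, 1, 1)),
                matrix(rnorm(18, 10), 6, 3)) + outer(rep(0, 12), c(0, 0, 0))
  vals[7:12, 3] <- vals[7:12, 3] + 15    # group difference only at level 3
  tab <- long_table(vals, rep(c("g1", "g2"), each = 6))
  se <- simple_effects_snk(tab, "m")
  expect_named(se$within_group, c("g1", "g2"))
  bg <- se$between_group
  expect_false(bg$significant[bg$fap_level == "0"])
  expect_true(bg$significant[bg$fap_level == "0.6"])
  expect_true(se$anova$effects$p[3] < 0.05)    # interaction driven design
})
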