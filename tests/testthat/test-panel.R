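test_that("panel construction validates ids, ranges and inconsistent anchors", {
  expect_error(make_panel(L = c(60, 105), H = c(70, 80)), "outside")
  expect_error(judge_panel(data.frame(judge_id = c("a", "a"),
                                      L = c(1, 2), H = c(3, 4))),
               "duplicate judge_id")
  expect_error(judge_panel(data.frame(judge_id = "a", L = 60)), "missing column")
  # L > H judges retained with a warning by default, droppable by switch
  expect_warning(p <- make_panel(L = c(70, 60), H = c(65, 80)), "retaining")
  expect_equal(nobs(p), 2)
  expect_warning(p2 <- make_panel(L = c(70, 60), H = c(65, 80),
                                  drop_inconsistent = TRUE), "dropping")
  expect_equal(nobs(p2), 1)
})

test_that("summarize_panel matches hand computation and a two-pass oracle", {
  # zero-variance panel
  s0 <- summarize_panel(make_panel(L = c(60, 60, 60), H = c(70, 70, 70)))
  expect_equal(s0$mean_L, 60)
  expect_equal(s0$sd_L, 0)
  expect_equal(s0$se_L, 0)
  expect_equal(s0$mean_H, 70)
  expect_equal(s0$se_H, 0)

  # two-judge hand computation: SD with n-1, SE = SD/sqrt(2)
  s2 <- summarize_panel(make_panel(L = c(60, 70), H = c(80, 90)))
  expect_equal(s2$mean_L, 65)
  expect_equal(s2$sd_L, sqrt(50), tolerance = 1e-12)
  expect_equal(s2$se_L, 5)

  # brute-force two-pass oracle on random panels
  two_pass <- function(v) {
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    c(m, s, s / sqrt(length(v)))
  }
  for (seed in 1:5) {
    p <- random_panel(n = 7 + seed, seed = seed)
    s <- summarize_panel(p)
    expect_equal(c(s$mean_L, s$sd_L, s$se_L), two_pass(p$ratings$L),
                 tolerance = 1e-12)
    expect_equal(c(s$mean_H, s$sd_H, s$se_H), two_pass(p$ratings$H),
                 tolerance = 1e-12)
  }
})

test_that("summary statistics are invariant to judge ordering", {
  p <- random_panel(12, seed = 42)
  set.seed(99)
  shuffled <- p
  shuffled$ratings <- p$ratings[sample(nrow(p$ratings)), ]
  a <- summarize_panel(p); b <- summarize_panel(shuffled)
  expect_equal(a[c("mean_L", "sd_L", "se_L", "mean_H", "sd_H", "se_H")],
               b[c("mean_L", "sd_L", "se_L", "mean_H", "sd_H", "se_H")])
})

test_that("suggested statistics appear only when every judge supplied one", {
  with_sug <- summarize_panel(make_panel(L = c(60, 62), H = c(70, 72),
                                         suggested = c(64, 66)))
  expect_equal(with_sug$mean_suggested, 65)
  partial <- suppressWarnings(
    make_panel(L = c(60, 62), H = c(70, 72), suggested = c(64, NA)))
  expect_true(is.na(summarize_panel(partial)$mean_suggested))
})

test_that("panels with fewer than 2 judges are rejected for summaries", {
  expect_error(summarize_panel(make_panel(L = 60, H = 70)),
               "insufficient panel")
})

test_that("trim_extremes removes whole judges by order statistics of one field", {
  p <- make_panel(L = c(10, 60, 61, 62, 99), H = c(50, 70, 71, 72, 100))
  expect_identical(trim_extremes(p, 0), p)
  t1 <- trim_extremes(p, 1, "L")
  expect_equal(t1$ratings$L, c(60, 61, 62))
  expect_equal(t1$ratings$H, c(70, 71, 72))     # whole judges removed
  expect_equal(t1$trimmed, c("j1", "j5"))
  expect_equal(p$ratings$L, c(10, 60, 61, 62, 99))  # original unchanged
  expect_error(trim_extremes(p, 2), "at least 2")
})

test_that("trimming then summarizing equals summarizing the filtered panel", {
  p <- random_panel(11, seed = 7)
  tr <- summarize_panel(trim_extremes(p, 2, "H"))
  ord <- order(p$ratings$H)
  keep <- p$ratings[sort(ord[3:9]), ]
  manual <- summarize_panel(judge_panel(keep))
  expect_equal(tr[c("mean_L", "se_L", "mean_H", "se_H")],
               manual[c("mean_L", "se_L", "mean_H", "se_H")])
})

test_that("bootstrap_se is zero on constants and reproducible by seed", {
  expect_equal(bootstrap_se(c(5, 5, 5, 5), replicates = 50, seed = 1), 0)
  a <- bootstrap_se(c(3, 9, 12, 20), replicates = 200, seed = 11)
  b <- bootstrap_se(c(3, 9, 12, 20), replicates = 200, seed = 11)
  expect_identical(a, b)
  expect_error(bootstrap_se(5, replicates = 10, seed = 1), "insufficient")
  expect_error(bootstrap_se(c(1, 2), replicates = 10), "seed")
})

test_that("bootstrap_se converges to the exhaustive-enumeration value at n = 2", {
  # with-replacement resamples of {0, 10}: means {0, 5, 5, 10}, equally
  # likely; the SD of that four-point distribution is the exact target
  means <- c(0, 5, 5, 10)
  exact <- sqrt(mean((means - mean(means))^2))  # population SD = 3.5355
  est <- bootstrap_se(c(0, 10), replicates = 20000, seed = 3)
  expect_equal(est, exact, tolerance = 0.02)
})

test_that("bootstrap SE approaches the analytic SD/sqrt(n) on normal data", {
  set.seed(17)
  v <- rnorm(17, 62.65, 23.12)
  analytic <- sd(v) / sqrt(17)
  boot <- bootstrap_se(v, replicates = 5000, seed = 5)
  expect_lt(abs(boot - analytic) / analytic, 0.15)
})

test_that("normality diagnostics report skewness and advise on clear departures", {
  d <- normality_diagnostics(c(1, 2, 3))
  expect_equal(d$skewness, 0)
  # right-skewed point mass: g1 = m3 / m2^1.5 computed by hand
  v <- c(1, 1, 1, 10)
  m2 <- mean((v - mean(v))^2); m3 <- mean((v - mean(v))^3)
  d2 <- normality_diagnostics(v)
  expect_equal(d2$skewness, m3 / m2^1.5, tolerance = 1e-12)
  expect_gt(d2$skewness, 1)
  expect_true(d2$advisory)
  expect_error(normality_diagnostics(c(1, 2)), "at least 3")
})

test_that("diagnostics rarely flag genuinely normal samples", {
  flags <- vapply(1:100, function(s) {
    set.seed(s)
    normality_diagnostics(rnorm(1000))$advisory
  }, logical(1))
  expect_gte(mean(!flags), 0.90)
})

test_that("doubling the panel leaves means fixed and shrinks SEs by ~1/sqrt(2)", {
  p <- random_panel(12, seed = 3)
  doubled <- p$ratings
  doubled$judge_id <- paste0(doubled$judge_id, "_copy")
  pd <- judge_panel(rbind(p$ratings, doubled))
  s1 <- summarize_panel(p); s2 <- summarize_panel(pd)
  expect_equal(s2$mean_L, s1$mean_L)
  expect_equal(s2$mean_H, s1$mean_H)
  expect_lt(abs(s2$se_L / s1$se_L - 1 / sqrt(2)), 0.05 / sqrt(2))
  expect_lt(abs(s2$se_H / s1$se_H - 1 / sqrt(2)), 0.05 / sqrt(2))
})
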