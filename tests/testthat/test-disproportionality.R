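# Independent oracles used here:
#  * Woolf log-odds-ratio standard error, written out from first principles;
#  * a Monte-Carlo sampler of the BCPNN posterior (independent Beta draws for
#    the cell and margin probabilities), written independently of the
#    package's own montecarlo variance model.

woolf_ci <- function(a, b, c, d, z = qnorm(0.975)) {
  lor <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(exp(lor - z * se), exp(lor + z * se))
}

mc_ic025_oracle <- function(a, b, c, d, ndraw = 2e5) {
  N <- a + b + c + d
  g <- 1 * (N + 2) * (N + 2) / ((a + b + 1) * (a + c + 1))
  ic <- log2(rbeta(ndraw, a + 1, N - a + g - 1)) -
    log2(rbeta(ndraw, a + b + 1, N - (a + b) + 1)) -
    log2(rbeta(ndraw, a + c + 1, N - (a + c) + 1))
  quantile(ic, 0.025, names = FALSE)
}

random_tables <- function(n, min_a = 0) {
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    N <- sample(200:50000, n, replace = TRUE)
    n1 <- pmax(10L, round(runif(n, 0.002, 0.2) * N))
    p <- runif(n, 0.001, 0.05)
    rr <- exp(runif(n, -1, 2.5))
    a <- rbinom(n, n1, pmin(1, p * rr))
    cc <- rbinom(n, N - n1, p)
    tab <- data.frame(a = a, b = n1 - a, c = cc, d = N - n1 - cc)
    tab <- tab[tab$a >= min_a & tab$b > 0 & tab$c > 0 & tab$d > 0, ]
    out <- rbind(out, tab)
  }
  out[seq_len(n), ]
}

test_that("contingency tables count reports once per distinct event", {
  te <- events_df(c("t1", "t1", "t2"), c("X", "X", "Y"))  # duplicate PT row
  be <- events_df(c("b1", "b2"), c("X", "Z"))
  tab <- contingency_tables(te, be, n_target = 2, n_background = 3)
  x <- tab[tab$term == "X", ]
  expect_equal(c(x$a, x$b, x$c, x$d), c(1, 1, 1, 2))
  # saturating event: in every report
  te2 <- events_df(c("t1", "t2"), c("X", "X"))
  be2 <- events_df(c("b1", "b2"), c("X", "X"))
  tab2 <- contingency_tables(te2, be2, 2, 2)
  expect_equal(c(tab2$b, tab2$d), c(0, 0))
  # absent event is a zero row, not an error
  tab3 <- contingency_tables(te, be, 2, 3, terms = "Nowhere")
  expect_equal(c(tab3$a, tab3$c), c(0, 0))
})

test_that("ROR point estimate and CI match the closed form", {
  r <- compute_ror(10, 90, 100, 9900)
  expect_equal(r$ror, 11.0, tolerance = 1e-12)
  expect_equal(r$ci_low, 5.56, tolerance = 0.01 / 5.56)
  expect_equal(r$ci_high, 21.77, tolerance = 0.01 / 21.77)
  expect_false(r$corrected)
  # symmetric tables: ror 1 for any k
  for (k in c(1, 3, 50)) expect_equal(compute_ror(k, k, k, k)$ror, 1)
  # swapping the rows inverts the odds ratio
  expect_equal(compute_ror(7, 13, 29, 41)$ror,
               1 / compute_ror(29, 41, 7, 13)$ror, tolerance = 1e-12)
})

test_that("ROR CI agrees with an independent log-OR oracle on 1000 tables", {
  set.seed(101)
  tabs <- random_tables(1000, min_a = 1)
  r <- compute_ror(tabs$a, tabs$b, tabs$c, tabs$d)
  for (i in seq_len(nrow(tabs))) {
    o <- woolf_ci(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(r$ci_low[i], o[1], tolerance = 1e-9)
    expect_equal(r$ci_high[i], o[2], tolerance = 1e-9)
  }
})

test_that("zero cells trigger the flagged Haldane-Anscombe correction", {
  r <- compute_ror(3, 0, 5, 100)
  expect_true(r$corrected)
  expect_equal(r$ror, (3.5 * 100.5) / (0.5 * 5.5), tolerance = 1e-12)
  manual_se <- sqrt(1 / 3.5 + 1 / 0.5 + 1 / 5.5 + 1 / 100.5)
  expect_equal(r$ci_low, exp(log(r$ror) - qnorm(0.975) * manual_se),
               tolerance = 1e-12)
  # degenerate margins are tagged, not NaN
  r2 <- compute_ror(0, 10, 0, 90)
  expect_false(r2$defined)
  expect_true(is.na(r2$ror))
})

test_that("independence tables give ROR 1 and raw IC 0", {
  set.seed(7)
  for (i in 1:25) {
    a <- sample(1:50, 1); b <- sample(1:200, 1); t <- sample(1:20, 1)
    r <- compute_ror(a, b, t * a, t * b)
    ic <- compute_ic(a, b, t * a, t * b)
    expect_equal(r$ror, 1, tolerance = 1e-12)
    expect_equal(ic$ic_raw, 0, tolerance = 1e-12)
  }
  # worked example: 1*110 == 10*11
  expect_equal(compute_ic(1, 9, 10, 90)$ic_raw, 0, tolerance = 1e-12)
})

test_that("raw IC matches the log2 observed/expected form", {
  ic <- compute_ic(10, 90, 100, 9900)
  expect_equal(ic$ic_raw, log2(10 * 10100 / (100 * 110)), tolerance = 1e-12)
  expect_equal(ic$ic_raw, 3.199, tolerance = 1e-3)
})

test_that("increasing a strictly increases ROR and raw IC", {
  base <- c(a = 10, b = 90, c = 100, d = 9900)
  r0 <- compute_ror(base["a"], base["b"], base["c"], base["d"])$ror
  r1 <- compute_ror(base["a"] + 1, base["b"], base["c"], base["d"])$ror
  expect_gt(r1, r0)
  i0 <- compute_ic(base["a"], base["b"], base["c"], base["d"])$ic_raw
  i1 <- compute_ic(base["a"] + 1, base["b"], base["c"], base["d"])$ic_raw
  expect_gt(i1, i0)
})

test_that("IC025 lies below E(IC) and tracks the posterior sampler", {
  set.seed(202)
  tabs <- random_tables(12, min_a = 3)
  closed <- compute_ic(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(closed$ic025 < closed$ic_expected))
  for (i in seq_len(nrow(tabs))) {
    oracle <- mc_ic025_oracle(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i],
                              ndraw = 1e5)
    expect_lt(abs(closed$ic025[i] - oracle), 0.2)
  }
  # the example table from the module contract
  ex <- compute_ic(5, 95, 50, 9850)
  expect_lt(abs(ex$ic025 - mc_ic025_oracle(5, 95, 50, 9850)), 0.15)
})

test_that("package montecarlo model agrees with its closed form", {
  set.seed(303)
  cl <- compute_ic(20, 480, 200, 19300)
  mc <- compute_ic(20, 480, 200, 19300, variance_model = "montecarlo",
                   n_draws = 2e5)
  expect_lt(abs(cl$ic_expected - mc$ic_expected), 0.02)
  expect_lt(abs(cl$ic025 - mc$ic025), 0.1)
})

test_that("degenerate IC margins are tagged undefined", {
  ic <- compute_ic(0, 0, 5, 95)
  expect_false(ic$defined)
  expect_true(is.na(ic$ic025))
})

test_that("dual criteria classify printed statistics correctly", {
  # a strong PT signal: N 166, CI lower 12.61, IC025 2.17
  strong <- apply_signal_criteria(166, 12.61, 2.17)
  expect_true(strong$of_interest)
  # a negative SOC: CI lower 0.75, IC025 -1.93
  weak <- apply_signal_criteria(817, 0.75, -1.93)
  expect_false(weak$ror_positive)
  expect_false(weak$ic_positive)
  expect_false(weak$of_interest)
  # N below 3 disqualifies regardless of effect size
  expect_false(apply_signal_criteria(2, 40, 3)$of_interest)
  expect_true(apply_signal_criteria(3, 1.01, 0.01)$of_interest)
})

test_that("screen output is ranked deterministically and annotated", {
  syn <- generate_faers(synthetic_config(seed = 21))
  coh <- select_cohort(build_cases(syn$bundles))
  sig <- screen_signals(coh, map = toy_pt_soc_map())
  expect_s3_class(sig, "faers_signals")
  expect_true(all(c("SOC", "PT") %in% sig$level))
  pt <- sig[sig$level == "PT", ]
  # every screened PT occurred at least once in the target cohort
  expect_true(all(pt$a >= 1))
  expect_true(all(pt$n == pt$a))
  # of_interest implies at least 3 reports
  expect_true(all(pt$a[pt$of_interest] >= 3))
  # within SOC, ROR is non-increasing
  for (s in unique(pt$soc)) {
    r <- pt$ror[pt$soc == s]
    expect_true(all(diff(r) <= 1e-12))
  }
  # expected annotation comes from the shipped list
  expect_true(all(pt$expected == (pt$term %in% expected_pts())))
  # excluded SOCs never appear
  expect_false(any(pt$soc %in% faers_excluded_socs()))
  expect_false(any(sig$soc[sig$level == "SOC"] %in% faers_excluded_socs()))
  # unmapped PTs are screened at PT level only
  expect_true("Feeling jittery" %in% pt$term)
  expect_false("UNMAPPED" %in% sig$soc[sig$level == "SOC"])
})

test_that("screening without a map degrades to PT level with a warning", {
  syn <- generate_faers(small_config(seed = 22))
  coh <- select_cohort(build_cases(syn$bundles))
  expect_warning(sig <- screen_signals(coh, map = NULL), "SOC-level")
  expect_true(all(sig$level == "PT"))
})
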