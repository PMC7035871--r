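# Locality-blocked permutation regression.

test_that("OLS recovers a noiseless line exactly", {
  g <- c(100, 150, 220, 300, 380)
  fit <- ols_fit(g, 2 + 0.1 * g)
  expect_equal(fit$r2, 1)
  expect_equal(fit$a, 2)
  expect_equal(fit$b, 0.1)
  expect_equal(fit$p, 0)
})

test_that("constant response gives zero slope and zero r2", {
  fit <- ols_fit(c(1, 2, 3, 4), rep(7, 4))
  expect_equal(fit$b, 0)
  expect_equal(fit$r2, 0)
})

test_that("OLS matches the lm oracle on fixed and random data", {
  g <- c(120, 180, 210, 290, 355)
  y <- c(10, 22, 15, 31, 40)
  fit <- ols_fit(g, y)
  orc <- summary(lm(y ~ g))
  expect_equal(fit$b, unname(coef(orc)["g", "Estimate"]), tolerance = 1e-12)
  expect_equal(fit$a, unname(coef(orc)["(Intercept)", "Estimate"]),
               tolerance = 1e-12)
  expect_equal(fit$r2, orc$r.squared, tolerance = 1e-12)
  expect_equal(fit$p, unname(coef(orc)["g", "Pr(>|t|)"]), tolerance = 1e-12)
  set.seed(77)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    g <- runif(n, 0, 400); y <- runif(n, 0, 100)
    fit <- ols_fit(g, y); orc <- summary(lm(y ~ g))
    expect_equal(fit$p, unname(coef(orc)["g", "Pr(>|t|)"]), tolerance = 1e-9)
    expect_equal(fit$r2, orc$r.squared, tolerance = 1e-9)
  }
})

test_that("degenerate OLS inputs are rejected", {
  expect_error(ols_fit(c(1, 2), c(1, 2)), "3 points")
  expect_error(ols_fit(rep(5, 10), runif(10)), "constant predictor")
})

test_that("one specimen per unit makes the permutation equal a single OLS fit", {
  set.seed(3)
  rec <- make_records(runif(20, 100, 400),
                      function(g, k) 5 + 0.08 * g + rnorm(k, 0, 5),
                      specimens = 1)
  perm <- permutation_regression(rec, season = "both", iterations = 50,
                                 seed = 2)
  fit <- ols_fit(rec$grassiness, rec$pct_c4)
  expect_equal(unname(perm$b["mean"]), fit$b, tolerance = 1e-12)
  expect_equal(unname(perm$r2["mean"]), fit$r2, tolerance = 1e-12)
  expect_equal(unname(perm$b["hi"] - perm$b["lo"]), 0, tolerance = 1e-12)
  expect_equal(perm$p_hat, 1 - as.numeric(fit$p < 0.05))
})

test_that("p-hat hits its endpoints", {
  # noiseless strong signal: every iteration's model p is 0 < 0.05
  rec <- make_records(seq(100, 400, length.out = 12),
                      function(g, k) rep(2 + 0.1 * g, k), specimens = 3)
  perm <- permutation_regression(rec, iterations = 100, seed = 1)
  expect_equal(perm$p_hat, 0)
  # pure noise: iteration-level significance is rare, p-hat stays high
  set.seed(9)
  rec2 <- make_records(runif(12, 100, 400), function(g, k) runif(k, 0, 100),
                       specimens = 4)
  perm2 <- permutation_regression(rec2, iterations = 200, seed = 1)
  expect_gte(perm2$p_hat, 0.8)
})

test_that("permutation draws are deterministic given the seed and stable across seeds", {
  set.seed(5)
  rec <- make_records(runif(30, 100, 400),
                      function(g, k) 5 + 0.08 * g + rnorm(k, 0, 10),
                      specimens = sample(1:8, 30, replace = TRUE))
  a <- permutation_regression(rec, iterations = 300, seed = 11)
  b <- permutation_regression(rec, iterations = 300, seed = 11)
  expect_identical(a$draws, b$draws)
  c <- permutation_regression(rec, iterations = 300, seed = 12)
  expect_false(identical(a$draws, c$draws))
  for (par in c("r2", "b")) {
    se <- sqrt(sd(a$draws[, par])^2 / 300 + sd(c$draws[, par])^2 / 300)
    expect_lt(abs(mean(a$draws[, par]) - mean(c$draws[, par])), 3 * se + 1e-9)
  }
})

test_that("n counts distinct locality x interval units", {
  rec <- rbind(
    make_records(c(150, 250, 350), function(g, k) rep(50, k), specimens = 4,
                 season = "dry", interval = "2003-06"),
    make_records(c(150, 250, 350), function(g, k) rep(50, k), specimens = 2,
                 season = "wet", interval = "2003-12"))
  # constant response is fine for counting; vary it slightly to allow fits
  set.seed(1); rec$pct_c4 <- rec$pct_c4 + rnorm(nrow(rec))
  both <- permutation_regression(rec, season = "both", iterations = 10, seed = 1)
  dry <- permutation_regression(rec, season = "dry", iterations = 10, seed = 1)
  wet <- permutation_regression(rec, season = "wet", iterations = 10, seed = 1)
  expect_equal(c(both$n, dry$n, wet$n), c(6, 3, 3))
})

test_that("blocked resampling removes bias from a heavily collected outlier locality", {
  # one locality contributes 50 outlying specimens; all others one each.
  # the naive all-specimen OLS is dragged off the generating slope, the
  # permuted mean stays close (the framework's purpose).
  set.seed(42)
  g <- seq(100, 400, length.out = 21)
  rec <- make_records(g, function(gi, k) 10 + 0.10 * gi + rnorm(k, 0, 2),
                      specimens = c(rep(1, 20), 50))
  out_l <- rec$locality_id == "L21"
  rec$pct_c4[out_l] <- 10 + 0.10 * rec$grassiness[out_l] - 40 +
    rnorm(sum(out_l), 0, 2)
  naive <- ols_fit(rec$grassiness, rec$pct_c4)
  perm <- permutation_regression(rec, iterations = 500, seed = 7)
  expect_lt(abs(unname(perm$b["mean"]) - 0.10), abs(naive$b - 0.10))
})

test_that("season comparison endpoints behave as specified", {
  dry <- matrix(0, 100, 4, dimnames = list(NULL, c("r2", "a", "b", "p")))
  wet <- dry
  dry[, "b"] <- 1; wet[, "b"] <- 0
  sep <- compare_seasons(dry, wet, "b")
  expect_lt(sep$p, 1 / 100)           # complete separation: below MC floor
  expect_gt(sep$p, 0)                 # never exactly zero
  same <- compare_seasons(dry, dry, "b")
  expect_equal(same$p, 0.5)           # exact null
  expect_error(compare_seasons(dry[1:50, ], wet, "b"), "differ")
})

test_that("a strong dry-wet slope contrast is detected one-tailed", {
  set.seed(6)
  gl <- runif(40, 100, 400)
  dry_rec <- make_records(gl, function(g, k) -2 + 0.10 * g + rnorm(k, 0, 8),
                          specimens = 3, season = "dry", interval = "2003-06")
  wet_rec <- make_records(gl, function(g, k) 37 + 0.01 * g + rnorm(k, 0, 8),
                          specimens = 3, season = "wet", interval = "2003-12")
  rec <- rbind(dry_rec, wet_rec)
  dry <- permutation_regression(rec, season = "dry", iterations = 400, seed = 1)
  wet <- permutation_regression(rec, season = "wet", iterations = 400, seed = 2)
  expect_lt(compare_seasons(dry, wet, "b")$p, 0.05)
  expect_lt(compare_seasons(dry, wet, "r2")$p, 0.05)
})

test_that("the full report covers every radius x season cell", {
  set.seed(8)
  gl2 <- runif(25, 100, 400); gl4 <- gl2 + rnorm(25, 0, 20)
  rec <- make_records(gl2, function(g, k) 10 + 0.05 * g + rnorm(k, 0, 10),
                      specimens = 2, season = "dry", interval = "2003-06")
  recw <- make_records(gl2, function(g, k) 30 + 0.02 * g + rnorm(k, 0, 10),
                       specimens = 2, season = "wet", interval = "2003-12")
  rec <- rbind(rec, recw)
  rec$grassiness_2km <- rec$grassiness
  rec$grassiness_4km <- c(rep(gl4, each = 2), rep(gl4, each = 2))
  rep_ <- permutation_report(rec, radii_km = c(2, 4), iterations = 50,
                             seed = 3)
  expect_equal(nrow(rep_$summaries), 6)   # 2 radii x both/dry/wet
  expect_equal(nrow(rep_$comparisons), 4) # 2 radii x {r2, b}
  expect_true(all(rep_$summaries$n == c(50, 25, 25)))
  expect_true(all(rep_$summaries$r2_lo <= rep_$summaries$r2_mean &
                    rep_$summaries$r2_mean <= rep_$summaries$r2_hi))
  expect_true(all(rep_$comparisons$p_one_tailed >= 0 &
                    rep_$comparisons$p_one_tailed <= 1))
  expect_error(permutation_report(rec, radii_km = c(2, 8)), "grassiness_8km")
})
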