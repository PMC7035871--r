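# Synthetic landscape and faecal-sample generator.

test_that("single-class mixture yields a uniform raster", {
  spec <- landscape_spec(width = 100, height = 100, cellsize = 30,
                         mixture = c(CG = 1), seed = 7)
  r <- generate_landscape(spec)
  cg <- savanna_scheme()$code[savanna_scheme()$abbrev == "CG"]
  expect_true(all(r$values == cg))
})

test_that("landscapes are deterministic given the seed", {
  spec <- landscape_spec(width = 60, height = 50, autocorr_len = 800,
                         seed = 42)
  expect_identical(generate_landscape(spec), generate_landscape(spec))
  spec2 <- landscape_spec(width = 60, height = 50, autocorr_len = 800,
                          seed = 43)
  expect_false(identical(generate_landscape(spec)$values,
                         generate_landscape(spec2)$values))
})

test_that("class proportions match the mixture within binomial sampling error", {
  # binomial oracle: se = sqrt(p(1-p)/n); rank-thresholding is in fact
  # exact to one cell, which sits far inside the 3 se band
  spec <- landscape_spec(width = 100, height = 100, autocorr_len = 0,
                         mixture = c(CDW = 0.5, CG = 0.5), seed = 5)
  p <- class_proportions(generate_landscape(spec)) / 100
  se <- sqrt(0.25 / 1e4)
  expect_true(all(abs(p - 0.5) <= 3 * se))
})

test_that("autocorrelated fields have same-class adjacency above independence", {
  mix <- c(CDW = 0.25, ODW = 0.25, DG = 0.25, CG = 0.25)
  spec <- landscape_spec(width = 120, height = 120, cellsize = 100,
                         autocorr_len = 1000, mixture = mix, seed = 9)
  v <- generate_landscape(spec)$values
  same_h <- mean(v[, -1] == v[, -ncol(v)])
  same_v <- mean(v[-1, ] == v[-nrow(v), ])
  expect_gt(same_h, sum(mix^2) + 0.1)
  expect_gt(same_v, sum(mix^2) + 0.1)
})

test_that("degenerate mixtures are rejected", {
  expect_error(landscape_spec(mixture = c(CG = 0, CDW = 0)), "degenerate")
  expect_error(landscape_spec(mixture = c(CG = -0.5, CDW = 1.5)),
               "non-negative")
  expect_error(landscape_spec(mixture = c(0.5, 0.5)), "named")
})

test_that("zero slope and zero noise give constant seasonal %C4", {
  r <- generate_landscape(landscape_spec(width = 60, height = 60,
                                         cellsize = 100, seed = 2))
  d <- diet_model_spec(a_dry = 20, b_dry = 0, a_wet = 55, b_wet = 0,
                       sd = 0, n_localities = 10, specimens = c(2, 2),
                       intervals = c("2003-06", "2003-12"),
                       reference_radius = 1000, seed = 3)
  s <- generate_samples(r, diet = d)
  expect_true(all(s$pct_c4_true[s$season == "dry"] == 20))
  expect_true(all(s$pct_c4_true[s$season == "wet"] == 55))
})

test_that("generated d13C round-trips through the mixing model", {
  r <- generate_landscape(landscape_spec(width = 60, height = 60,
                                         cellsize = 100, seed = 2))
  d <- diet_model_spec(n_localities = 15, reference_radius = 1000, seed = 8,
                       intervals = c("2003-02", "2003-07"))
  s <- generate_samples(r, diet = d)
  back <- pct_c4(s$d13C, d$params)
  expect_equal(back$pct_c4, s$pct_c4_true, tolerance = 1e-9)
  expect_true(all(s$pct_c4_true >= 0 & s$pct_c4_true <= 100))
})

test_that("sample generation is deterministic and rejects impossible placement", {
  r <- generate_landscape(landscape_spec(width = 40, height = 40,
                                         cellsize = 100, seed = 2))
  d <- diet_model_spec(n_localities = 8, reference_radius = 800, seed = 5,
                       intervals = "2003-06")
  expect_identical(generate_samples(r, diet = d),
                   generate_samples(r, diet = d))
  d_big <- diet_model_spec(n_localities = 40 * 40 + 1, seed = 1)
  expect_error(generate_samples(r, diet = d_big), "placement")
})

test_that("season mapping follows the May-October dry convention", {
  expect_identical(season_of(c("2003-05", "2003-10", "2003-11", "2004-04")),
                   c("dry", "dry", "wet", "wet"))
  expect_error(season_of("2003-13"), "YYYY-MM")
})

test_that("OLS slope estimates recover the generating dry-season slope", {
  # simulation oracle: the 95% CI of the per-dataset OLS fit should cover
  # the generating slope in >= 90% of seeded replicates
  r <- generate_landscape(landscape_spec(width = 80, height = 80,
                                         cellsize = 100,
                                         autocorr_len = 1500, seed = 21))
  hits <- 0L; n_rep <- 100L
  for (i in seq_len(n_rep)) {
    d <- diet_model_spec(b_dry = 0.10, sd = 10, n_localities = 100,
                         specimens = c(1, 1), intervals = "2003-06",
                         reference_radius = 1500, seed = 1000 + i)
    s <- generate_samples(r, diet = d)
    fit <- lm(pct_c4_true ~ grassiness_ref, data = s)
    ci <- confint(fit)["grassiness_ref", ]
    if (ci[1] <= 0.10 && 0.10 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
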