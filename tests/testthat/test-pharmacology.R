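test_that("MPA transform handles its boundary cases and is invertible", {
  expect_equal(compute_mpa(2, 2, 26), 0)
  expect_equal(compute_mpa(26, 2, 26), 100)
  expect_equal(compute_mpa(14, 2, 26), 50)
  expect_error(compute_mpa(5, 2, 2), "equal")
  # unclipped by default, clipped on request
  expect_lt(compute_mpa(1, 2, 26), 0)
  expect_equal(compute_mpa(1, 2, 26, clip = TRUE), 0)
  # round trip through the inverse
  for (m in c(-10, 0, 37.5, 100, 120))
    expect_close(compute_mpa(wd50_from_mpa(m, 2, 26), 2, 26), m, 1e-12)
})

test_that("Hill fit recovers noiseless parameters and the half-max identity", {
  truth <- hill_params(6, 31, 1, 0.43)
  d <- rep(doses_a, each = 3)
  fit <- fit_hill(d, hill_response(d, truth))
  expect_close(fit$params$y0, truth$y0, 1e-5)
  expect_close(fit$params$ymax, truth$ymax, 1e-5)
  expect_close(fit$params$h, truth$h, 1e-5)
  expect_lt(abs(fit$params$ec50 - truth$ec50) / truth$ec50, 1e-5)
  expect_close(hill_response(truth$ec50, truth), (truth$y0 + truth$ymax) / 2, 1e-12)
  expect_error(fit_hill(c(0, 1, 2), c(1, 2, 3)), "4 distinct")
})

test_that("excluding the collapsing dose reduces EC50 bias", {
  truth <- hill_params(6, 31, 1, 0.43)
  col <- collapse_params(c50 = 10, h_col = 2)
  set.seed(21)
  bias <- replicate(200, {
    tr <- behavioral_truth(truth, col, n_animals = 6, noise_sd = 5,
                           seed = sample.int(1e6, 1))
    tab <- gen_behavioral(tr, doses_a)$table
    f_in <- tryCatch(fit_hill(tab$dose_mgkg, tab$mpa)$params$ec50,
                     error = function(e) NA)
    f_ex <- tryCatch(fit_hill(tab$dose_mgkg, tab$mpa, exclude = 20)$params$ec50,
                     error = function(e) NA)
    c(inc = f_in, exc = f_ex)
  })
  err <- abs(log(bias / truth$ec50))
  expect_lt(median(err["exc", ], na.rm = TRUE), median(err["inc", ], na.rm = TRUE))
})

test_that("EC50 recovery accuracy at the in-vivo design scale", {
  # design scale: 8 doses, 8 animals, hourly testing over 4 h with
  # 5% MPA noise per measurement, reduced to each animal's 4-h-max MPA;
  # the median absolute relative EC50 error over 200 replicates stays
  # under 15%
  truth <- hill_params(6, 31, 1, 0.43)
  set.seed(31)
  err <- replicate(200, {
    tr <- behavioral_truth(truth, NULL, n_animals = 8, noise_sd = 5,
                           seed = sample.int(1e6, 1))
    tab <- gen_behavioral(tr, doses_a)$table
    agg <- mpa_by_animal(tab, "max_4h")
    f <- tryCatch(fit_hill(agg$dose_mgkg, agg$mpa)$params$ec50,
                  error = function(e) NA)
    abs(f - truth$ec50) / truth$ec50
  })
  expect_lt(median(err, na.rm = TRUE), 0.15)
  expect_lt(mean(is.na(err)), 0.05)
})

test_that("Hill-times-collapse model fits and recovers the collapse dose", {
  truth <- hill_params(6, 31, 1, 0.4)
  col <- collapse_params(c50 = 10, h_col = 2)
  d <- rep(c(0, 0.05, 0.15, 0.4, 1.1, 3.3, 10, 20), each = 8)
  # structural identities
  expect_equal(collapse_factor(0, col), 1)
  expect_equal(collapse_factor(col$c50, col), 0.5)
  expect_equal(hill_response(0.4, truth, NULL), hill_response(0.4, truth))
  # noiseless refit
  f0 <- fit_hill_collapse(unique(d), hill_response(unique(d), truth, col),
                          fixed_ymax = truth$ymax)
  expect_lt(abs(f0$collapse$c50 - col$c50) / col$c50, 1e-3)
  expect_lt(abs(f0$hill$ec50 - truth$ec50) / truth$ec50, 1e-3)
  # noisy recovery at the in-vivo design scale (simulation oracle: the
  # median relative C50 error at 2% noise, 8x8 design, is well under 25%)
  set.seed(41)
  err <- replicate(100, {
    yy <- hill_response(d, truth, col) + rnorm(length(d), 0, 2)
    f <- tryCatch(fit_hill_collapse(d, yy, fixed_ymax = truth$ymax)$collapse$c50,
                  error = function(e) NA)
    abs(f - col$c50) / col$c50
  })
  expect_lt(median(err, na.rm = TRUE), 0.25)
})

test_that("dose equivalence reproduces the closed-form worked case", {
  a <- hill_params(0, 100, 1, 1)
  b <- hill_params(0, 50, 1, 10)
  expect_close(dose_equivalent(10, a, b), 1 / 3, 1e-12)
  expect_equal(dose_equivalent(0, a, b), 0)
  expect_close(additive_response(0, 10, a, b), 25, 1e-9)
  expect_equal(additive_response(3, 0, a, b), hill_response(3, a))
  # identical drugs: a_eq is the identity
  expect_close(dose_equivalent(7, a, a), 7, 1e-9)
  expect_error(dose_equivalent(1, b, a), "ymax_a >= ymax_b")
})

test_that("equal-efficacy drugs give a symmetric additive response", {
  a <- hill_params(2, 60, 1, 1)
  b <- hill_params(2, 60, 1, 5)
  for (da in c(0.3, 1)) for (db in c(2, 8)) {
    expect_close(additive_response(da, db, a, b),
                 additive_response(db, da, b, a), 1e-9)
  }
  # occupancy oracle for H = 1: effects through equivalent occupancy agree
  occ <- function(d, p) (d / p$ec50) / (1 + d / p$ec50)
  da <- 0.4; db <- 3
  d_tot <- da + dose_equivalent(db, a, b)
  direct <- a$y0 + (a$ymax - a$y0) * occ(d_tot, a)
  expect_close(additive_response(da, db, a, b), direct, 1e-9)
})

test_that("interaction classification follows the sign outside the band", {
  expect_equal(classify_interaction(48, 30, 3), "synergistic")
  expect_equal(classify_interaction(30, 30, 3), "additive")
  expect_equal(classify_interaction(20, 30, 3), "antagonistic")
  expect_equal(classify_interaction(31, 30, 3), "additive")
})

test_that("isobole endpoints, consistency and A50 behave", {
  a <- hill_params(6, 31.2, 1, 0.43)
  b <- hill_params(6, 22.9, 1, 29.4)
  iso <- isobole_a50(a, b, ratio_b_over_a = 55)
  # endpoint invariants
  expect_close(iso$curve$a[1], 0, 1e-12)
  expect_close(dose_equivalent(iso$curve$b[1], a, b), a$ec50, 1e-6)
  expect_close(iso$curve$a[nrow(iso$curve)], a$ec50, 1e-12)
  expect_close(iso$curve$b[nrow(iso$curve)], 0, 1e-6)
  # every isobole point maps to the half-max additive effect
  target <- (a$y0 + a$ymax) / 2
  for (i in seq(1, nrow(iso$curve), by = 20))
    expect_close(additive_response(iso$curve$a[i], iso$curve$b[i], a, b),
                 target, 1e-6)
  # A50 lies on the ray and on the isobole
  expect_close(iso$a50_theoretical[["b"]],
               55 * iso$a50_theoretical[["a"]], 1e-9)
  expect_close(additive_response(iso$a50_theoretical[["a"]],
                                 iso$a50_theoretical[["b"]], a, b),
               target, 1e-6)
  # identical drugs on a 1:1 ray split the EC50 evenly
  iso2 <- isobole_a50(a, a, ratio_b_over_a = 1)
  expect_close(iso2$a50_theoretical[["a"]], a$ec50 / 2, 1e-6)
  # a synergistic observed combination lies below the additive A50
  obs <- hill_params(a$y0, a$ymax, 1, iso$a50_theoretical[["a"]] / 2)
  iso3 <- isobole_a50(a, b, 55, observed_fit = obs)
  expect_lt(iso3$a50_observed[["a"]], iso3$a50_theoretical[["a"]])
  expect_lt(iso3$a50_observed[["b"]], iso3$a50_theoretical[["b"]])
})

test_that("E-score sums five bounded ratings", {
  expect_equal(escore(c(2, 2, 2, 2, 2))$total, 10)
  expect_equal(escore(c(0, 0, 0, 0, 0))$total, 0)
  expect_equal(escore(c(1, 0, 2, 1, 0))$total, 4)
  expect_error(escore(c(1, 2, 3, 0, 0)), "ratings")
  expect_error(escore(c(1, 1, 1, 1)), "five")
})
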