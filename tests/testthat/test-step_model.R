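mk_track <- function(t, x, y, ...) data.frame(t = t, x = x, y = y, ...)

test_that("resampling regularizes bursts and flags sparse tracks", {
  # 10-minute data: kept fixes exactly 3600 s apart
  tt <- seq(0, 6 * 3600, by = 600)
  tr <- resample_track(mk_track(tt, seq_along(tt), 0), tolerance = 300)
  expect_true(all(diff(tr$t) == 3600))
  expect_true(attr(tr, "usable"))

  # already-hourly data is unchanged
  hh <- mk_track(seq(0, 10 * 3600, by = 3600), 1:11, 0)
  out <- resample_track(hh)
  expect_equal(out[, c("t", "x", "y")], hh)

  # a 5-hour gap starts a new burst
  gap <- mk_track(c(0:3, 8:11) * 3600, 1:8, 0)
  out <- resample_track(gap)
  expect_equal(unique(out$burst), 1:2)
  expect_equal(sum(out$burst == 1), 4L)

  expect_warning(res <- resample_track(mk_track(c(0, 3600), 1:2, 0)),
                 "unusable")
  expect_false(attr(res, "usable"))
})

test_that("the speed filter removes only implausible arrivals", {
  # 55.6 m/s over one hour: arriving fix dropped
  two <- mk_track(c(0, 3600), c(0, 200000), 0)
  out <- speed_filter(two)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_removed"), 1L)

  slow <- mk_track((0:5) * 3600, (0:5) * 1000, 0)
  expect_equal(nrow(speed_filter(slow)), 6L)
  expect_equal(attr(speed_filter(slow), "n_removed"), 0L)

  # a single 200 km spike (55.6 m/s) among hourly kilometre steps: only the
  # spike goes
  spike <- mk_track((0:6) * 3600, c(0, 1000, 2000, 202000, 3000, 4000, 5000),
                    0)
  out <- speed_filter(spike)
  expect_equal(nrow(out), 6L)
  expect_false(202000 %in% out$x)
})

test_that("step construction gets lengths and turn angles right", {
  east2 <- mk_track((0:2) * 3600, c(0, 1000, 2000), c(0, 0, 0))
  st <- build_steps(east2)
  expect_equal(st$length, c(1000, 1000))
  expect_true(is.na(st$turn[1]))
  expect_equal(st$turn[2], 0)

  # east then north: turn +pi/2
  en <- mk_track((0:2) * 3600, c(0, 1000, 1000), c(0, 0, 1000))
  expect_equal(build_steps(en)$turn[2], pi / 2)

  # zero-length step: bearing carried forward to the following turn
  z <- mk_track((0:3) * 3600, c(0, 1000, 1000, 2000), c(0, 0, 0, 0))
  st <- build_steps(z)
  expect_true(is.na(st$bearing[2]))
  expect_equal(st$turn[3], 0) # straight on, relative to carried bearing
})

test_that("the pooled exponential rate is the closed-form MLE", {
  expect_equal(fit_step_length_distribution(c(1000, 3000)), 1 / 2000)
  expect_equal(fit_step_length_distribution(rep(500, 9)), 1 / 500)
  expect_error(fit_step_length_distribution(c(0, 0)), "zero")

  set.seed(50)
  draws <- rexp(10000, 1 / 500)
  expect_lt(abs(fit_step_length_distribution(draws) - 1 / 500) / (1 / 500),
            0.03)
})

test_that("available steps follow the declared availability kernel", {
  st <- data.frame(x1 = 0, y1 = 0, x2 = 300, y2 = 400, length = 500,
                   prev_bearing = 0.3, turn = 0.1)
  s <- generate_available_steps(st, n_avail = 10, rate = 1 / 500, seed = 51)
  expect_equal(nrow(s), 11L)
  expect_equal(sum(s$is_used), 1L)
  expect_true(s$is_used[1])

  big <- generate_available_steps(st, n_avail = 100000, rate = 1 / 500,
                                  seed = 52)
  expect_lt(abs(mean(big$length[-1]) - 500) / 500, 0.01)
  ks <- suppressWarnings(
    stats::ks.test(big$turn[-1][1:10000], "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)

  st$prev_bearing <- NA_real_
  expect_error(generate_available_steps(st, rate = 1 / 500), "bearing")
})

test_that("dissimilarity is a planar metric in PC space", {
  toy <- toy_pca()
  # natal at scores (0,0), location at (3,4) -> 5
  natal <- c(0, 0)
  # construct the habitat vector whose scores are (3, 4) by inverting the
  # projection: z = L %*% s for orthonormal L, then v = means + sds * z
  z <- toy$loadings %*% c(3, 4)
  v <- setNames(as.numeric(toy$means + toy$sds * z), toy$variables)
  expect_equal(unname(project_habitat(toy, v)), c(3, 4), tolerance = 1e-12)
  expect_equal(compute_dissimilarity(toy, natal, v), 5, tolerance = 1e-12)

  # identity and symmetry
  expect_equal(compute_dissimilarity(toy, project_habitat(toy, v), v), 0,
               tolerance = 1e-9)
  w <- setNames(as.numeric(toy$means + toy$sds *
                             (toy$loadings %*% c(-1, 2))), toy$variables)
  expect_equal(compute_dissimilarity(toy, project_habitat(toy, v), w),
               compute_dissimilarity(toy, project_habitat(toy, w), v),
               tolerance = 1e-12)
})

test_that("distance to nest is Euclidean in kilometres", {
  expect_equal(compute_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(compute_distance(c(0, 0), c(3000, 4000)), 5)
  p <- rbind(c(1000, 0), c(2000, 0), c(3000, 0))
  expect_equal(compute_distance(c(0, 0), p), c(1, 2, 3))
})

test_that("standardization is exact, reversible and recorded", {
  d <- data.frame(stratum = 1, is_used = c(TRUE, FALSE),
                  dissimilarity = c(0, 2), distance = c(1, 3))
  z <- standardize_design(d)
  expect_equal(z$dissimilarity_z, c(-1, 1) / sqrt(2), tolerance = 1e-9)
  sc <- attr(z, "scaling")
  expect_equal(sc$sd[sc$covariate == "dissimilarity"], sqrt(2))

  fx <- shared_fixture()
  z <- standardize_design(fx$design)
  expect_lt(abs(mean(z$dissimilarity_z)), 1e-12)
  expect_equal(sd(z$dissimilarity_z), 1, tolerance = 1e-12)
  expect_true(abs(attr(z, "correlation")[1, 2]) <= 1)

  # back-transform: refit on the raw scale reproduces beta_z / sd
  fit_z <- fit_clogit(z, c("dissimilarity_z", "distance_z"))
  fit_raw <- fit_clogit(z, c("dissimilarity", "distance"))
  sc <- attr(z, "scaling")
  expect_equal(fit_z$coefficients$beta / sc$sd, fit_raw$coefficients$beta,
               tolerance = 1e-6)

  d$distance <- c(2, 2)
  expect_error(standardize_design(d), "distance")
})

test_that("design bookkeeping: 11 rows per stratum, one used each", {
  fx <- shared_fixture()
  des <- fx$design
  tab <- table(des$stratum)
  expect_true(all(tab == 11))
  expect_equal(nrow(des), 11 * length(unique(des$stratum)))
  used <- tapply(des$is_used, des$stratum, sum)
  expect_true(all(used == 1))
  expect_equal(length(unique(des$stratum)),
               sum(is.finite(fx$steps$prev_bearing)))
})
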