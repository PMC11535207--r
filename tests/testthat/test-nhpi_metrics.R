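test_that("the point metrics reproduce their closed forms", {
  expect_equal(nhpi_average(c(1, -1)), 0)
  expect_equal(nhpi_average(c(0.5, 0.5, 0.5)), 0.5)
  expect_error(nhpi_average(numeric(0)), "empty")

  expect_equal(nhpi_specialization(c(1, -1)), 1) # bimodal: average is 0
  expect_equal(nhpi_specialization(rep(0, 5)), 0)

  expect_equal(nhpi_heterogeneity(c(1, -1)), sqrt(2), tolerance = 1e-12)
  expect_equal(nhpi_heterogeneity(rep(0.3, 4)), 0)
  expect_error(nhpi_heterogeneity(1), "at least 2")

  expect_equal(nhpi_consistency(c(1, -2), c(1, -2)), 0)
  expect_equal(nhpi_consistency(c(1, 0), c(0, 1)), 1)

  expect_equal(nhpi_reversal(c(1, 1), c(-1, 1)), 0.5)
  expect_equal(nhpi_reversal(c(1, 2, 3), c(4, 5, 6)), 0)
  # sign(0) counts as positive
  expect_equal(nhpi_reversal(0, -1), 1)
  expect_equal(nhpi_reversal(0, 1), 0)

  rec <- data.frame(id = "a", year = c(1, 2, 4), x = c(1, 2, 4))
  expect_equal(nhpi_interannual_consistency(rec), 1.5)
  rec2 <- data.frame(id = rep(c("a", "b"), each = 2), year = c(1, 2, 1, 2),
                     x = c(0, 1, 0, 3))
  expect_equal(nhpi_interannual_consistency(rec2), 2)
  const <- data.frame(id = rep(c("a", "b"), each = 3), year = rep(1:3, 2),
                      x = rep(c(2, -1), each = 3))
  expect_equal(nhpi_interannual_consistency(const), 0)
  expect_warning(
    nhpi_interannual_consistency(
      data.frame(id = c("a", "a", "b"), year = c(1, 2, 1), x = 1:3)),
    "fewer than 2")
})

test_that("metric inequalities and symmetries hold on random inputs", {
  set.seed(70)
  for (i in 1:1000) {
    x <- rnorm(sample(2:20, 1), sd = runif(1, 0.1, 3))
    expect_gte(nhpi_specialization(x), abs(nhpi_average(x)))
  }
  x <- rnorm(50); xp <- rnorm(25); xs <- rnorm(25)
  expect_equal(nhpi_average(-x), -nhpi_average(x))
  expect_equal(nhpi_specialization(-x), nhpi_specialization(x))
  expect_equal(nhpi_heterogeneity(-x), nhpi_heterogeneity(x))
  expect_equal(nhpi_consistency(-xp, -xs), nhpi_consistency(xp, xs))
  expect_equal(nhpi_reversal(-xp, -xs), nhpi_reversal(xp, xs))
  expect_equal(nhpi_consistency(xs, xp), nhpi_consistency(xp, xs))
  expect_gte(min(nhpi_reversal(xp, xs), 1 - nhpi_reversal(xp, xs)), 0)

  # independent two-pass SD oracle
  for (i in 1:20) {
    x <- rnorm(30)
    mu <- sum(x) / length(x)
    oracle <- sqrt(sum((x - mu)^2) / (length(x) - 1))
    expect_equal(nhpi_heterogeneity(x), oracle, tolerance = 1e-12)
  }
})

test_that("incomplete pairs are excluded with a warning", {
  expect_warning(v <- nhpi_consistency(c(1, NA, 3), c(2, 2, 2)), "incomplete")
  expect_equal(v, mean(c(1, 1)))
  expect_error(suppressWarnings(nhpi_consistency(NA, 1)), "no complete")
})

test_that("uncertainty propagation collapses, reproduces, and is calibrated", {
  rec <- simulate_coefficients(30, mean = 0.4, sd = 0.6, se_scale = 0,
                               seed = 71)
  md <- propagate_uncertainty(rec, n_sim = 50, seed = 72)
  for (key in names(attr(md, "replicates"))) {
    pt <- md$point[paste(md$metric, md$group, sep = "|") == key]
    expect_true(all(attr(md, "replicates")[[key]] == pt)) # se = 0: exact
  }

  # determinism
  rec$se <- 0.3
  a <- propagate_uncertainty(rec, n_sim = 100, seed = 73)
  b <- propagate_uncertainty(rec, n_sim = 100, seed = 73)
  expect_identical(attr(a, "replicates"), attr(b, "replicates"))

  # single record, se = 1: replicate SD of the average is close to 1
  one <- data.frame(x = 0.2, se = 1)
  md <- propagate_uncertainty(one, metrics = "average", n_sim = 1e5,
                              seed = 74)
  reps <- attr(md, "replicates")[["average|pooled"]]
  expect_lt(abs(sd(reps) - 1), 0.02)
  expect_lt(abs(mean(reps) - 0.2), 0.02) # unbiased under symmetric noise

  # missing SE: excluded with warning
  rec$se[1] <- NA
  expect_warning(propagate_uncertainty(rec, n_sim = 10, seed = 75),
                 "excluding 1")
})

test_that("uncertainty propagation respects groups and pair metrics", {
  rec <- rbind(
    data.frame(id = sprintf("a%d", 1:10), phase = "p", x = 1, se = 0,
               habitat = "low"),
    data.frame(id = sprintf("a%d", 1:10), phase = "s", x = -1, se = 0,
               habitat = "low"),
    data.frame(id = sprintf("b%d", 1:10), phase = "p", x = 2, se = 0,
               habitat = "high"),
    data.frame(id = sprintf("b%d", 1:10), phase = "s", x = 2, se = 0,
               habitat = "high"))
  md <- propagate_uncertainty(rec, metrics = c("consistency", "reversal"),
                              by = "habitat", n_sim = 5, seed = 76)
  get <- function(m, g) md$point[md$metric == m & md$group == g]
  expect_equal(get("consistency", "low"), 2)
  expect_equal(get("reversal", "low"), 1)
  expect_equal(get("consistency", "high"), 0)
  expect_equal(get("reversal", "high"), 0)
})

test_that("group comparison matches the textbook one-way ANOVA", {
  # 3 groups, n = 5 each, hand-checkable F statistic
  v <- c(1, 2, 3, 4, 5,   4, 5, 6, 7, 8,   1, 1, 2, 2, 4)
  g <- rep(c("a", "b", "c"), each = 5)
  means <- tapply(v, g, mean); gm <- mean(v)
  ssb <- 5 * sum((means - gm)^2)
  ssw <- sum((v - means[g])^2)
  f_oracle <- (ssb / 2) / (ssw / 12)
  res <- compare_groups(v, g)
  expect_equal(unname(res$tukey$cells[, 1]),
               unname(c(means["b"] - means["a"], means["c"] - means["a"],
                        means["c"] - means["b"])), tolerance = 1e-9)
  expect_equal(unname(anova(aov(v ~ factor(g)))[1, "F value"]), f_oracle,
               tolerance = 1e-9)
  expect_equal(res$omnibus_p, pf(f_oracle, 2, 12, lower.tail = FALSE),
               tolerance = 1e-9)

  # separation: distinct letters; identical groups: no letters
  far <- compare_groups(c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01)),
                        rep(c("a", "b"), each = 10))
  expect_false(far$letters[["a"]] == far$letters[["b"]])
  same <- compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_null(same$letters)
  expect_error(compare_groups(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("two-way comparisons label habitat-by-phase cells", {
  set.seed(77)
  hab <- rep(c("low", "high"), each = 40)
  ph <- rep(rep(c("p", "s"), each = 20), 2)
  v <- rnorm(80, ifelse(hab == "low" & ph == "s", 3, 0), 0.5)
  res <- compare_groups(v, hab, ph)
  expect_lt(res$omnibus_p, 0.05)
  expect_equal(length(res$letters), 4L)
  lets <- res$letters
  odd <- lets[["low:s"]]
  others <- lets[setdiff(names(lets), "low:s")]
  expect_false(any(vapply(others, function(l)
    any(strsplit(l, "")[[1]] %in% strsplit(odd, "")[[1]]), TRUE)))
})
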