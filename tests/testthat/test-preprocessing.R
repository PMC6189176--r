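make_raw_cohort <- function(J_ctl = 120, J_pat = 80, age_slope = -2,
                            seed = 70) {
  set.seed(seed)
  J <- J_ctl + J_pat
  age <- runif(J, 50, 80)
  sex <- rbinom(J, 1, 0.5)
  control <- rep(c(TRUE, FALSE), c(J_ctl, J_pat))
  # volume declines with age in everyone; patients lose extra volume
  vol <- 100 + age_slope * (age - 65) + rnorm(J, 0, 5)
  vol[!control] <- vol[!control] - runif(J_pat, 0, 40)
  flat <- 50 + rnorm(J, 0, 4) # no covariate effect, no disease effect
  data.frame(vol = vol, flat = flat, age = age, sex = sex,
             control = control)
}

test_that("controls are mean 0, SD 1 after the transform", {
  raw <- make_raw_cohort()
  adj <- fit_control_adjustment(raw, c("vol", "flat"), raw$control,
                                covariates = c("age", "sex"))
  z <- to_zscores(raw, adj, decline_direction = TRUE)
  zc <- z$values[raw$control, ]
  expect_lt(max(abs(colMeans(zc))), 1e-8)
  expect_lt(max(abs(apply(zc, 2, sd) - 1)), 1e-8)
})

test_that("a planted age effect is recovered and regressed out", {
  raw <- make_raw_cohort(age_slope = -2)
  adj <- fit_control_adjustment(raw, "vol", raw$control,
                                covariates = c("age", "sex"))
  p <- adj$per_biomarker$vol
  expect_true("age" %in% p$covariates)
  slope <- p$coef[[grep("age", names(p$coef))]]
  expect_lt(abs(slope - (-2)) / 2, 0.1)
  z <- to_zscores(raw, adj)
  r <- cor(z$values[raw$control, "vol"], raw$age[raw$control])
  expect_lt(abs(r), 0.05)
})

test_that("null covariates are screened out at the nominal rate", {
  excluded <- 0
  for (trial in 1:100) {
    set.seed(700 + trial)
    ctl <- data.frame(y = rnorm(60), junk = rnorm(60),
                      control = TRUE)
    adj <- fit_control_adjustment(ctl, "y", ctl$control,
                                  covariates = "junk")
    if (!"junk" %in% adj$per_biomarker$y$covariates) excluded <- excluded + 1
  }
  expect_gte(excluded, 90) # alpha = 0.05 screen
})

test_that("the sign flip maps decline onto positive abnormality", {
  set.seed(71)
  raw <- data.frame(vol = rnorm(60, 100, 10), control = TRUE)
  adj <- fit_control_adjustment(raw, "vol", raw$control)
  p <- adj$per_biomarker$vol
  new <- data.frame(vol = p$mean - 2 * p$sd) # two control SDs below mean
  z <- to_zscores(new, adj, decline_direction = TRUE)
  expect_equal(unname(z$values[1, 1]), 2)
  z_noflip <- to_zscores(new, adj, decline_direction = FALSE)
  expect_equal(unname(z_noflip$values[1, 1]), -2)
})

test_that("the transform is affine and rank preserving, and not repeatable", {
  raw <- make_raw_cohort()
  adj <- fit_control_adjustment(raw, c("vol", "flat"), raw$control)
  z <- to_zscores(raw, adj)
  # no covariates retained or not: within-biomarker ranks must be reversed
  # exactly (decline flip) relative to raw when no covariate is removed
  adj0 <- fit_control_adjustment(raw, "flat", raw$control)
  z0 <- to_zscores(raw, adj0)
  expect_equal(order(z0$values[, "flat"]), order(raw$flat, decreasing = TRUE))
  expect_error(to_zscores(z, adj), "twice")
})

test_that("unusable biomarkers are flagged and dropped", {
  raw <- data.frame(good = rnorm(40), bad = rep(3, 40), control = TRUE)
  adj <- fit_control_adjustment(raw, c("good", "bad"), raw$control)
  expect_false(adj$per_biomarker$bad$usable)
  z <- to_zscores(raw, adj)
  expect_equal(colnames(z$values), "good")
})

test_that("control adjustments survive a JSON round trip", {
  raw <- make_raw_cohort()
  adj <- fit_control_adjustment(raw, c("vol", "flat"), raw$control,
                                covariates = c("age", "sex"))
  path <- tempfile(fileext = ".json")
  write_control_adjustment(adj, path)
  adj2 <- read_control_adjustment(path)
  z1 <- to_zscores(raw, adj)
  z2 <- to_zscores(raw, adj2)
  expect_equal(z1$values, z2$values)
})

test_that("event selection applies the minimum-count and z_max rules", {
  # counts above z = (1:50, 2:12, 3:8) -> events {1,2}, z_max = 3
  v1 <- c(runif(8, 3.1, 4), runif(4, 2.1, 3), runif(38, 1.1, 2),
          runif(50, -1, 1))
  # counts (1:40, 2:30, 3:15) -> events {1,2,3}, z_max = 5
  v2 <- c(runif(15, 3.1, 4), runif(15, 2.1, 3), runif(10, 1.1, 2),
          runif(60, -1, 1))
  # counts (1:9, 2:3, 3:0) -> biomarker dropped
  v3 <- c(runif(3, 2.1, 3), runif(6, 1.1, 2), runif(91, -1, 1))
  X <- cbind(a = v1, b = v2, c = v3)
  expect_warning(es <- select_events(X, rep(TRUE, 100)), "dropped")
  expect_equal(es$n_biomarkers, 2)
  expect_equal(es$events$z[es$events$biomarker_name == "a"], c(1, 2))
  expect_equal(es$z_max[match("a", es$biomarker_names)], 3)
  expect_equal(es$events$z[es$events$biomarker_name == "b"], c(1, 2, 3))
  expect_equal(es$z_max[match("b", es$biomarker_names)], 5)
  expect_equal(attr(es, "kept_biomarkers"), c(1, 2))
  # retained sets are always prefixes because exceedance is nested
  set.seed(72)
  Xr <- matrix(rnorm(200 * 3, 1, 2), 200, 3)
  es_r <- select_events(Xr, rep(TRUE, 200), min_count = 5)
  for (i in seq_len(es_r$n_biomarkers)) {
    zi <- es_r$events$z[es_r$events$biomarker == i]
    expect_equal(zi, seq_along(zi))
  }
  expect_error(select_events(X[, 3, drop = FALSE], rep(TRUE, 100)),
               "no biomarker")
})

test_that("the asymmetry helper log transforms the hemispheric difference", {
  expect_equal(hemispheric_asymmetry(110, 90), log(20 / 200))
  expect_equal(hemispheric_asymmetry(100, 100), log(1e-6))
  expect_error(hemispheric_asymmetry(-1, 2), "positive")
})
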