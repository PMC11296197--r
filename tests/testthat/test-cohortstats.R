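toy_cohort <- function() {
  tibble::tibble(
    sample = sprintf("S%02d", 1:6),
    sex = c("M", "M", "M", "F", "F", "F"),
    x = c(1, 2, 3, 10, 20, 30)
  )
}

test_that("sex standardisation gives per-sex mean zero and unit sd", {
  tb <- sex_standardize(toy_cohort(), "x")
  expect_equal(tb$x_z, c(-1, 0, 1, -1, 0, 1))
  set.seed(2)
  big <- tibble::tibble(sex = rep(c("M", "F"), c(53, 29)),
                        v = rnorm(82, 5, 3))
  z <- sex_standardize(big, "v")$v_z
  for (s in c("M", "F")) {
    expect_equal(mean(z[big$sex == s]), 0, tolerance = 1e-10)
    expect_equal(sd(z[big$sex == s]), 1, tolerance = 1e-10)
  }
  # constant-within-sex column rejected by name
  bad <- tibble::tibble(sex = rep(c("M", "F"), each = 3),
                        ind = rep(c(1, 0), each = 3))
  expect_error(sex_standardize(bad, "ind"), "ind")
})

test_that("sex mean and variance tests match hand-computed statistics", {
  same <- tibble::tibble(sex = rep(c("M", "F"), each = 4),
                         v = rep(c(1, 2, 3, 4), 2))
  r <- sex_mean_variance_tests(same, "v")
  expect_equal(r$value[r$statistic == "t"], 0)
  expect_equal(r$p_value[r$statistic == "t"], 1)
  expect_equal(r$value[r$statistic == "F"], 1)
  # pooled-variance t for {0,0,1,1} vs {10,10,11,11}: |t| = 10 * sqrt(6)
  d <- tibble::tibble(sex = rep(c("M", "F"), each = 4),
                      v = c(0, 0, 1, 1, 10, 10, 11, 11))
  r2 <- sex_mean_variance_tests(d, "v")
  expect_equal(abs(r2$value[r2$statistic == "t"]), 24.4948974278,
               tolerance = 1e-9)
  expect_equal(r2$df1[r2$statistic == "t"], 6)
})

test_that("the variance-ratio F test detects a genuine variance difference", {
  set.seed(17)
  hits <- vapply(1:200, function(i) {
    d <- tibble::tibble(sex = rep(c("M", "F"), c(53, 29)),
                        v = c(rnorm(53, 0, 1), rnorm(29, 0, 2)))
    r <- sex_mean_variance_tests(d, "v")
    r$p_value[r$statistic == "F"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Pearson matrix reports exact limits and calibrated estimates", {
  set.seed(8)
  x <- rnorm(30)
  tb <- tibble::tibble(a = x, b = -x, c = rnorm(30))
  pm <- pearson_matrix(tb, c("a", "b", "c"))
  expect_equal(pm$r["a", "a"], 1)
  expect_equal(pm$r["a", "b"], -1)
  expect_lt(pm$p["a", "b"], 1e-12)
  # mean correlation estimate is unbiased for rho = 0.55 at n = 82
  set.seed(9)
  rhat <- vapply(1:300, function(i) {
    u <- rnorm(82); v <- 0.55 * u + sqrt(1 - 0.55^2) * rnorm(82)
    pearson_matrix(tibble::tibble(u = u, v = v), c("u", "v"))$r["u", "v"]
  }, numeric(1))
  expect_lt(abs(mean(rhat) - 0.55), 0.03)
  expect_error(pearson_matrix(tibble::tibble(a = rep(1, 5), b = 1:5),
                              c("a", "b")), "constant")
})

test_that("backward elimination keeps real effects and drops noise terms", {
  set.seed(11)
  n <- 82
  d <- data.frame(sex = rep(c("M", "F"), c(53, 29)),
                  x = rnorm(n), z = rnorm(n))
  d$y <- 2 * d$x + rnorm(n, 0, 0.1)
  r <- glm_backward_reintroduce(d, "y", c("x", "z", "x:sex"))
  tt <- r$table
  expect_true(tt$retained[tt$term == "x"])
  expect_false(tt$retained[tt$term == "z"])
  expect_false(tt$retained[tt$term == "x:sex"])
  expect_true(all(c("F", "df1", "df2", "p_value") %in% names(tt)))
  # every candidate term reported exactly once
  expect_setequal(tt$term, c("x", "z", "x:sex"))
})

test_that("a perfectly explanatory term yields an overwhelming F", {
  d <- data.frame(x = seq(-1, 1, length.out = 40), z = rnorm(40))
  d$y <- d$x
  r <- glm_backward_reintroduce(d, "y", c("x", "z"))
  tt <- r$table
  expect_gt(tt$F[tt$term == "x"], 1e10)
  expect_lt(tt$p_value[tt$term == "x"], 1e-12)
  expect_false(tt$retained[tt$term == "z"])
})

test_that("alpha = 1 keeps the full model and alpha = 0 strips it", {
  set.seed(12)
  d <- data.frame(y = rnorm(30), x = rnorm(30), z = rnorm(30))
  full <- glm_backward_reintroduce(d, "y", c("x", "z"), alpha = 1)
  expect_true(all(full$table$retained))
  none <- glm_backward_reintroduce(d, "y", c("x", "z"), alpha = 0)
  expect_true(!any(none$table$retained))
  expect_equal(length(coef(none$final_model)), 1) # intercept only
  # aliased designs are rejected with the offending term named
  d$x2 <- d$x
  expect_error(glm_backward_reintroduce(d, "y", c("x", "x2")), "alias")
})

test_that("marginality protects main effects of retained interactions", {
  set.seed(13)
  n <- 120
  d <- data.frame(sex = rep(c("M", "F"), each = n / 2), x = rnorm(n))
  # pure interaction signal, weak main effect
  d$y <- ifelse(d$sex == "M", 1.5, -1.5) * d$x + rnorm(n, 0, 0.5)
  r <- glm_backward_reintroduce(d, "y", c("x", "sex", "x:sex"))
  tt <- r$table
  expect_true(tt$retained[tt$term == "x:sex"])
  expect_true(tt$retained[tt$term == "x"])
  expect_true(tt$retained[tt$term == "sex"])
})

test_that("varimax orthogonalisation decorrelates collinear predictors", {
  set.seed(14)
  n <- 82
  u <- rnorm(n)
  tb <- tibble::tibble(p = u + 0.3 * rnorm(n), q = u + 0.3 * rnorm(n))
  expect_gt(cor(tb$p, tb$q), 0.8)
  vo <- varimax_orthogonalize(tb, c("p", "q"))
  expect_lt(abs(cor(vo$scores$RC1, vo$scores$RC2)), 1e-8)
  # rotated loading basis is orthonormal
  ltl <- t(vo$loadings) %*% vo$loadings
  expect_lt(max(abs(ltl - diag(2))), 1e-8)
  expect_error(varimax_orthogonalize(tibble::tibble(a = rep(1, 5), b = 1:5),
                                     c("a", "b")), "constant")
})

test_that("male-line residuals expose only unexplained dichromatism", {
  set.seed(15)
  n1 <- 53; n2 <- 29
  sex <- rep(c("M", "F"), c(n1, n2))
  x <- rnorm(n1 + n2)
  y <- 3 + 2 * x + ifelse(sex == "M", rnorm(n1 + n2, 0, 0.5), 0)
  tb <- tibble::tibble(sex = sex, x = x, y = y)
  # put the females exactly on the fitted male line: both sexes then have
  # zero mean residual and the t statistic vanishes
  mcoef <- coef(lm(y ~ x, data = tb[tb$sex == "M", ]))
  tb$y[tb$sex == "F"] <- mcoef[1] + mcoef[2] * tb$x[tb$sex == "F"]
  r <- male_residual_dichromatism(tb, "y", "x")
  expect_equal(r$test$value, 0, tolerance = 1e-8)
  expect_equal(unname(unlist(r$mean_residuals[, "mean_residual"])), c(0, 0),
               tolerance = 1e-10)
  # a +5 female offset off the male line is recovered in the residuals
  tb2 <- tb
  tb2$y <- tb2$y + ifelse(tb2$sex == "F", 5, 0) + rnorm(n1 + n2, 0, 0.5)
  r2 <- male_residual_dichromatism(tb2, "y", "x")
  fem <- r2$mean_residuals$mean_residual[r2$mean_residuals$sex == "F"]
  expect_lt(abs(fem - 5), 0.5)
  expect_lt(r2$test$p_value, 1e-6)
  expect_error(male_residual_dichromatism(tb[tb$sex == "F", ], "y", "x"),
               "male")
})

test_that("residual correction removes a fully mediated sex difference", {
  set.seed(16)
  hits <- vapply(1:100, function(i) {
    n1 <- 53; n2 <- 29
    sex <- rep(c("M", "F"), c(n1, n2))
    # one within-sex sd of structural dichromatism, fully mediating
    x <- rnorm(n1 + n2, mean = ifelse(sex == "M", 0.5, -0.5))
    y <- 2 * x + rnorm(n1 + n2, 0, 1) # same line in both sexes
    r <- male_residual_dichromatism(tibble::tibble(sex = sex, x = x, y = y),
                                    "y", "x")
    r$test$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("paired hue comparison handles exact and offset predictions", {
  tb <- tibble::tibble(sex = rep(c("M", "F"), c(5, 4)),
                       hue = c(371, 375, 380, 369, 373, 390, 385, 388, 392))
  tb$predicted_hue <- tb$hue
  r <- paired_hue_comparison(tb)
  expect_equal(r$interaction$t, 0)
  expect_equal(r$per_sex$mean_difference, c(0, 0))
  expect_equal(r$per_sex$t, c(0, 0))
  # constant +8 female overestimation, males exact
  tb2 <- tb
  tb2$predicted_hue <- tb2$hue + ifelse(tb2$sex == "F", 8, 0)
  r2 <- paired_hue_comparison(tb2)
  expect_equal(r2$per_sex$mean_difference[r2$per_sex$sex == "F"], 8)
  expect_equal(r2$per_sex$mean_difference[r2$per_sex$sex == "M"], 0)
  expect_equal(r2$interaction$p_value, 0) # no within-sex scatter at all
  tb2$predicted_hue[1] <- NA
  expect_error(paired_hue_comparison(tb2), "estimated")
})

test_that("repeatability is exact for identical rounds and detects sex gaps", {
  set.seed(18)
  r1 <- tibble::tibble(sample = sprintf("S%02d", 1:48),
                       sex = rep(c("M", "F"), each = 24),
                       q1 = rnorm(48, 0.045, 0.002),
                       h1 = rnorm(48, 0.008, 0.001))
  rep1 <- suppressWarnings(repeatability(r1, r1, c("q1", "h1")))
  expect_equal(rep1$r, c(1, 1), tolerance = 1e-12)
  expect_error(repeatability(r1, dplyr::mutate(r1, sample = paste0("X", sample)),
                             "q1"), "overlap")
  # strongly repeatable in one sex, weakly in the other: interaction detected
  hits <- vapply(1:100, function(i) {
    x <- rnorm(48)
    rho <- ifelse(r1$sex == "F", 0.97, 0.3)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(48)
    ra <- dplyr::mutate(r1, v = x)
    rb <- dplyr::mutate(r1, v = y)
    out <- repeatability(ra, rb, "v")
    out$interaction_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("t and r statistics are invariant to affine rescaling", {
  set.seed(19)
  tb <- tibble::tibble(sex = rep(c("M", "F"), c(10, 10)),
                       v = rnorm(20), w = rnorm(20))
  r1 <- sex_mean_variance_tests(tb, "v")
  tb2 <- dplyr::mutate(tb, v = 100 * v + 7)
  r2 <- sex_mean_variance_tests(tb2, "v")
  expect_equal(r1$value, r2$value, tolerance = 1e-10)
  p1 <- pearson_matrix(tb, c("v", "w"))$r[1, 2]
  p2 <- pearson_matrix(dplyr::mutate(tb, v = 3 * v - 2, w = w / 5),
                       c("v", "w"))$r[1, 2]
  expect_equal(p1, p2, tolerance = 1e-12)
})
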