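test_that("cervid index standardizes pellet groups to 100 m2", {
  mk_pellets <- function(counts, area = 100, surveyed = rep(TRUE, 16),
                         transect = "T01", class = "large") {
    validate_table(data.frame(
      transect_id = transect, year = 2016L, plot_id = 1:16,
      plot_area_m2 = area, species_class = class, pellet_groups = counts,
      surveyed = surveyed, stringsAsFactors = FALSE), "pellet_counts")
  }
  ## 16 plots of 100 m2 with 32 groups: 32 / 1600 m2 = 2.0 per 100 m2
  p <- mk_pellets(c(rep(2L, 16)))
  expect_equal(cervid_index(p)$cervid_index, 2.0)

  ## 11 of 16 plots surveyed: transect excluded (< 12)
  p11 <- mk_pellets(rep(1L, 16), surveyed = c(rep(TRUE, 11), rep(FALSE, 5)))
  expect_equal(nrow(cervid_index(p11)), 0)
  p12 <- mk_pellets(rep(1L, 16), surveyed = c(rep(TRUE, 12), rep(FALSE, 4)))
  expect_equal(nrow(cervid_index(p12)), 1)

  ## index above 25 removed as an outlier
  p26 <- mk_pellets(rep(26L, 16))
  expect_equal(nrow(cervid_index(p26)), 0)
  p25 <- mk_pellets(rep(25L, 16))
  expect_equal(cervid_index(p25)$cervid_index, 25)

  ## splitting a plot's count across two rows of the same area is neutral
  split_rows <- rbind(mk_pellets(rep(1L, 16)), mk_pellets(rep(1L, 16)))
  split_rows$pellet_groups <- c(rep(1L, 16), rep(1L, 16))
  expect_equal(cervid_index(split_rows)$cervid_index,
               cervid_index(mk_pellets(rep(2L, 16)))$cervid_index)

  ## 10 m2 plots contribute their own area within their class
  small <- mk_pellets(rep(1L, 16), area = 10, class = "small")
  expect_equal(cervid_index(small)$cervid_index, 16 / 160 * 100)
})

test_that("boundary adjustment compresses the unit interval", {
  expect_equal(boundary_adjust(1, 100), 0.995)
  expect_equal(boundary_adjust(0, 100), 0.005)
  expect_equal(boundary_adjust(0.5, 10), 0.5)
  expect_equal(boundary_adjust(0.5, 1e6), 0.5)
})

test_that("beta regression MLE matches a brute-force likelihood grid", {
  set.seed(13)
  ## intercept-only: mu = 0.62, phi = 20
  n <- 50
  y <- rbeta(n, 0.62 * 20, 0.38 * 20)
  fit <- betareg_fit(y)
  b_grid <- seq(-1.5, 2.5, length.out = 200)
  lp_grid <- seq(log(2), log(200), length.out = 40)
  ll <- outer(b_grid, lp_grid, Vectorize(function(b, lp)
    beta_loglik_oracle(b, logphi = lp, y = y)))
  best <- arrayInd(which.max(ll), dim(ll))
  cell_b <- diff(b_grid)[1]
  expect_lt(abs(fit$coefficients$estimate[1] - b_grid[best[1]]), cell_b)
  expect_lt(abs(log(fit$phi) - lp_grid[best[2]]), diff(lp_grid)[1])
  ## optimizer improved on (or matched) its start
  expect_gte(fit$logLik, fit$logLik_start - 1e-8)

  ## one-predictor grid
  x <- rnorm(n)
  mu <- plogis(0.3 + 0.8 * x)
  y2 <- rbeta(n, mu * 25, (1 - mu) * 25)
  fit2 <- betareg_fit(y2, cbind(x = x))
  b0g <- seq(-1, 1.5, length.out = 100)
  b1g <- seq(-0.5, 2, length.out = 100)
  lpg <- seq(log(3), log(150), length.out = 20)
  ll2 <- array(dim = c(100, 100, 20))
  for (k in seq_along(lpg))
    ll2[, , k] <- outer(b0g, b1g, Vectorize(function(a, b)
      beta_loglik_oracle(a, b, lpg[k], y2, x)))
  best2 <- arrayInd(which.max(ll2), dim(ll2))
  expect_lt(abs(fit2$coefficients$estimate[1] - b0g[best2[1]]),
            diff(b0g)[1])
  expect_lt(abs(fit2$coefficients$estimate[2] - b1g[best2[2]]),
            diff(b1g)[1])
})

test_that("beta regression rejects degenerate inputs", {
  set.seed(14)
  y <- rbeta(30, 2, 2)
  x <- rnorm(30)
  expect_error(betareg_fit(y, cbind(x, x)), "rank-deficient")
  expect_error(betareg_fit(c(y, 0)), "strictly inside")
  expect_error(betareg_fit(y[1:3], cbind(x = x[1:3], z = rnorm(3))),
               "observations")
})

test_that("drivers analysis skips small strata and flags collinearity", {
  set.seed(15)
  n <- 100
  cov <- validate_table(data.frame(
    transect_id = sprintf("T%02d", 1:n),
    cervid_index = rgamma(n, 4, 1),
    habitat_shannon = rnorm(n, 2, 0.2),
    arable_prop = runif(n, 0, 0.4), stringsAsFactors = FALSE), "covariates")
  mk_overlap <- function(tr, season, pianka) validate_table(data.frame(
    transect_id = tr, season = season, landscape = "boreo_nemoral",
    kind = "intra", species_a = "moose", species_b = "moose",
    pianka = pianka, n_samples_a = 3L, n_samples_b = 3L,
    stringsAsFactors = FALSE), "overlap")
  ## a stratum with 5 < 8 transects is skipped with a note
  ov_small <- mk_overlap(cov$transect_id[1:5], "spring",
                         rbeta(5, 5, 2))
  res <- drivers_analysis(ov_small, cov)
  expect_null(res$fits)
  expect_match(res$skipped$note, "insufficient")

  ## a large stratum fits; intercept row present; n recorded
  ov_big <- mk_overlap(cov$transect_id, "winter", rbeta(n, 5, 2))
  res2 <- drivers_analysis(ov_big, cov)
  expect_equal(unique(res2$fits$n), n)
  expect_true("(Intercept)" %in% res2$fits$term)
  expect_null(res2$collinearity_flags)

  ## engineered predictor correlation well above 0.3 is flagged
  cov2 <- cov
  cov2$habitat_shannon <- pmax(
    0.1, 1.5 + 0.5 * scale(cov2$cervid_index)[, 1] + rnorm(n, 0, 0.3))
  stopifnot(abs(cor(cov2$cervid_index, cov2$habitat_shannon)) > 0.3)
  res3 <- drivers_analysis(ov_big, validate_table(cov2, "covariates"))
  expect_false(is.null(res3$collinearity_flags))
})

test_that("a simulated density effect on overlap is recovered in sign", {
  ## small-scale sign-recovery check: logit(mu) = -0.5 + 0.3 * density
  set.seed(16)
  hits <- 0L
  for (rep in 1:20) {
    n <- 30
    dens <- rgamma(n, 4, 1)
    mu <- plogis(-0.5 + 0.3 * dens)
    y <- rbeta(n, mu * 40, (1 - mu) * 40)
    fit <- betareg_fit(y, cbind(cervid_index = dens))
    est <- fit$coefficients
    if (est$estimate[est$term == "cervid_index"] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 19)
})
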