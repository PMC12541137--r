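test_that("default spec encodes the study's community structure", {
  spec <- make_default_spec()
  pool <- spec$taxon_pool
  expect_equal(nrow(pool), 210)
  expect_equal(length(unique(pool$family)), 77)

  mu_bn <- stratum_mean_diet(spec, "moose", "winter", "boreo_nemoral")
  mu_cb <- stratum_mean_diet(spec, "moose", "winter", "coastal_boreal")
  pine <- pool$motu_id[pool$category == "pine"]
  gram <- pool$motu_id[pool$category == "graminoids"]
  expect_gt(sum(mu_bn[pine]), 0.5)
  expect_gt(sum(mu_cb[pine]), 0.35)
  expect_lt(sum(mu_cb[pine]), 0.40)
  for (season in c("spring", "summer_autumn", "winter"))
    for (ls in c("coastal_boreal", "boreo_nemoral"))
      expect_lt(sum(stratum_mean_diet(spec, "moose", season, ls)[gram]),
                0.01)
  ## every stratum mean is a simplex vector
  expect_equal(sum(mu_bn), 1, tolerance = 1e-12)
})

test_that("simulation is deterministic given the master seed", {
  spec <- small_spec()
  a <- simulate_dataset(spec, seed = 11)
  b <- simulate_dataset(spec, seed = 11)
  expect_identical(a$read_counts, b$read_counts)
  expect_identical(a$sample_metadata, b$sample_metadata)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$pellet_counts, b$pellet_counts)
  c <- simulate_dataset(spec, seed = 12)
  expect_false(identical(a$read_counts, c$read_counts))
})

test_that("without overdispersion and at high depth replicate RRA matches the latent diet", {
  spec <- small_spec(replicate_overdispersion = 0,
                     depth_meanlog = log(2e7), depth_sdlog = 0,
                     low_depth_rate = 0, control_like_rate = 0,
                     expected_samples = rbind(
                       coastal_boreal = c(moose = 1, roe = 0, red = 0,
                                          fallow = 0),
                       boreo_nemoral = c(moose = 1, roe = 0, red = 0,
                                         fallow = 0)))
  sim <- simulate_dataset(spec, seed = 3)
  rc <- sim$read_counts
  plant <- rc[rc$marker == "plant" & rc$control_kind == "none", ]
  m <- count_matrix(plant)
  cols <- intersect(colnames(m), names(sim$truth))
  rra <- m[, cols] / rowSums(m)
  truth <- as.matrix(sim$truth[match(plant$sample_id, sim$truth$sample_id),
                               cols])
  expect_lt(max(abs(rra - truth)), 1e-3)
})

test_that("zero contamination gives clean controls", {
  spec <- small_spec(contamination = c(extraction_blank = 0,
                                       pcr_negative = 0, pcr_positive = 0,
                                       primer_blank = 0),
                     expected_samples = rbind(
                       coastal_boreal = c(moose = 0.5, roe = 0, red = 0,
                                          fallow = 0),
                       boreo_nemoral = c(moose = 0.5, roe = 0, red = 0,
                                         fallow = 0)))
  sim <- simulate_dataset(spec, seed = 5)
  ctrl <- sim$read_counts[sim$read_counts$control_kind != "none", ]
  expect_gt(nrow(ctrl), 0)
  expect_true(all(rowSums(count_matrix(ctrl)) == 0))
})

test_that("latent diets recover the stratum Dirichlet mean", {
  ## >= 200 samples in one stratum; mean latent diet within 3 Monte-Carlo SE
  spec <- small_spec(expected_samples = rbind(
    coastal_boreal = c(moose = 0, roe = 0, red = 0, fallow = 0),
    boreo_nemoral = c(moose = 60, roe = 0, red = 0, fallow = 0)))
  sim <- simulate_dataset(spec, seed = 9)
  meta <- sim$sample_metadata
  win <- meta$sample_id[meta$season == "winter"]
  expect_gte(length(win), 200)
  tr <- as.matrix(sim$truth[match(win, sim$truth$sample_id),
                            spec$taxon_pool$motu_id])
  mu <- stratum_mean_diet(spec, "moose", "winter", "boreo_nemoral")
  dev <- abs(colMeans(tr) - mu)
  ## structural zeros of the mean diet are recovered exactly
  expect_true(all(dev[mu == 0] == 0))
  ## against the theoretical Dirichlet Monte-Carlo SE,
  ## sd = sqrt(mu (1 - mu) / (conc + 1)), the bulk of components sit within
  ## 3 SE (a few excursions among 210 components are expected) and none far
  ## outside
  conc <- spec$diet_concentration[["winter"]]
  se_th <- sqrt(mu * (1 - mu) / (conc + 1) / nrow(tr))
  z <- dev[mu > 0] / se_th[mu > 0]
  expect_gte(mean(z <= 3), 0.98)
  expect_true(all(z <= 6))
})

test_that("the simulated cervid index matches the landscape means", {
  spec <- make_default_spec()
  ## pool three independent pellet simulations to shrink Monte-Carlo error
  ci <- do.call(rbind, lapply(21:23, function(s)
    cervid_index(cervidDiet:::.make_pellets(spec, s))))
  bn <- ci$cervid_index[startsWith(ci$transect_id, "BN")]
  cb <- ci$cervid_index[startsWith(ci$transect_id, "CB")]
  expect_gte(length(bn) / 3, 45)
  expect_lt(abs(mean(bn) - 4.88) / 4.88, 0.10)
  ## low-density landscape: absolute check, the mean is near zero
  expect_lt(abs(mean(cb) - 0.43), 0.2)
  ## predictors drawn independently: screening correlation below 0.3
  sim <- simulate_dataset(spec, seed = 21)
  cc <- cor(sim$covariates[, c("cervid_index", "habitat_shannon",
                               "arable_prop")])
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.3))
})
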