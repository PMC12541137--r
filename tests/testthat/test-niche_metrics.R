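test_that("richness counts strictly positive taxa per sample", {
  prof <- profile_from_matrix(rbind(S1 = c(A = 0.5, B = 0.5, C = 0),
                                    S2 = c(A = 1, B = 0, C = 0)))
  meta <- tiny_metadata(c("S1", "S2"))
  r <- richness(prof, meta)
  expect_equal(r$S, c(2L, 1L))
  ## dropping a taxon column (and renormalizing) never increases S
  sub <- to_rra(prof[, c("sample_id", "A", "B")])
  expect_true(all(richness(sub, meta)$S <= r$S))
})

test_that("Dunn z statistics follow the mid-rank formula with BH adjustment", {
  ## identical value multisets: z = 0, p = 1
  d0 <- dunn_bh(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)

  ## {1,2,3} vs {4,5,6}: mid-ranks 2 vs 5, N = 6, no ties:
  ## z = 3 / sqrt((6*7/12) * (2/3)) = 1.963961..., two-sided p = 0.04956
  d1 <- dunn_bh(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(abs(d1$z), 3 / sqrt(3.5 * 2 / 3), tolerance = 1e-12)
  expect_equal(d1$p, 2 * pnorm(-3 / sqrt(3.5 * 2 / 3)), tolerance = 1e-12)

  ## tie correction: pooled ties shrink the variance term
  vals <- c(1, 2, 2, 3, 2, 4)
  dt <- dunn_bh(vals, rep(c("a", "b"), each = 3))
  N <- 6; Tc <- (3^3 - 3) / (12 * (N - 1))
  r <- rank(vals)
  zexp <- (mean(r[1:3]) - mean(r[4:6])) /
    sqrt((N * (N + 1) / 12 - Tc) * (2 / 3))
  expect_equal(dt$z, zexp, tolerance = 1e-12)

  ## BH step-up over three pairs: (0.01, 0.02, 0.04) -> (0.03, 0.03, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  set.seed(4)
  d3 <- dunn_bh(rnorm(30), rep(c("a", "b", "c"), each = 10))
  expect_equal(d3$p_adj, p.adjust(d3$p, "BH"))
  expect_true(all(d3$p_adj >= d3$p))

  ## groups below 2 observations are excluded with a warning
  expect_warning(dunn_bh(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "excluding")
})

test_that("Dunn statistics agree with a permutation oracle on tiny fixtures", {
  ## brute force: all assignments of 6 values to two groups of 3; the
  ## permutation tail probability of |rank-mean difference| must order the
  ## pairs identically to the normal-approximation p
  set.seed(8)
  vals <- c(2.1, 3.5, 1.2, 7.7, 8.1, 6.9, 4.4, 5.0)
  grp <- rep(c("a", "b"), each = 4)
  d <- dunn_bh(vals, grp)
  r <- rank(vals)
  obs <- abs(mean(r[grp == "a"]) - mean(r[grp == "b"]))
  combs <- combn(8, 4)
  perm <- apply(combs, 2, function(i) abs(mean(r[i]) - mean(r[-i])))
  p_perm <- mean(perm >= obs - 1e-12)
  ## the normal approximation tracks the exact tail and agrees in sign
  expect_lt(abs(p_perm - d$p), 0.1)
  expect_equal(sign(d$z), sign(mean(r[grp == "a"]) - mean(r[grp == "b"])))
})

test_that("DNW is the Hill number of the average diet", {
  uni <- profile_from_matrix(rbind(S1 = rep(0.25, 4)))
  colnames(uni)[-1] <- c("A", "B", "C", "D")
  expect_equal(dnw(uni), 4)
  single <- profile_from_matrix(rbind(S1 = c(A = 1, B = 0)))
  expect_equal(dnw(single), 1)
  half <- profile_from_matrix(rbind(S1 = c(A = 0.5, B = 0.5)))
  expect_equal(dnw(half), 2)

  ## 1 <= DNW <= S, equality with S only at uniformity
  set.seed(2)
  for (i in 1:20) {
    p <- as.numeric(cervidDiet:::.rdirichlet1(rep(0.6, 8)))
    prof <- profile_from_matrix(matrix(p, 1, dimnames = list("S1",
                                                             letters[1:8])))
    v <- dnw(prof)
    expect_gte(v, 1)
    expect_lte(v, sum(p > 0) + 1e-9)
  }
})

test_that("Pianka's index matches its closed form and properties", {
  expect_equal(pianka(c(0.4, 0.3, 0.2, 0.1), c(0.4, 0.3, 0.2, 0.1)), 1)
  expect_equal(pianka(c(1, 0, 0), c(0, 0.5, 0.5)), 0)
  expect_equal(pianka(c(0.5, 0.5), c(1, 0)), 0.5 / sqrt(0.5),
               tolerance = 1e-12)
  expect_error(pianka(c(0, 0), c(1, 0)), "zero vector")
  set.seed(3)
  for (i in 1:25) {
    u <- as.numeric(cervidDiet:::.rdirichlet1(rep(1, 6)))
    v <- as.numeric(cervidDiet:::.rdirichlet1(rep(1, 6)))
    expect_equal(pianka(u, v), pianka(v, u), tolerance = 1e-12)
    expect_equal(pianka(u, u), 1, tolerance = 1e-12)
    expect_true(pianka(u, v) >= 0 && pianka(u, v) <= 1)
  }
})

test_that("Jacob's D matches its closed form and is antisymmetric", {
  expect_equal(jacobs_d(0, 0.5), -1)
  expect_equal(jacobs_d(0.3, 0), 1)
  expect_equal(jacobs_d(0.3, 0.3), 0)
  expect_equal(jacobs_d(0.2, 0.1), 0.1 / 0.26, tolerance = 1e-12)
  expect_true(is.na(jacobs_d(0, 0)))
  expect_true(is.na(jacobs_d(1, 1)))
  set.seed(5)
  r <- runif(30); p <- runif(30)
  expect_equal(jacobs_d(r, p), -jacobs_d(p, r), tolerance = 1e-12)
  expect_true(all(abs(jacobs_d(r, p)) <= 1 + 1e-12))
})

test_that("transect-scale overlap averages sample pairs and flags sparse cells", {
  m <- rbind(S1 = c(A = 0.5, B = 0.5, C = 0),
             S2 = c(A = 0.5, B = 0.5, C = 0),
             S3 = c(A = 0, B = 0.5, C = 0.5))
  prof <- profile_from_matrix(m)
  meta <- tiny_metadata(c("S1", "S2", "S3"))
  ov <- overlap_table(prof, meta, mode = "intra")
  a <- pianka(m[1, ], m[3, ])
  expect_equal(ov$pianka, (1 + 2 * a) / 3, tolerance = 1e-12)
  expect_equal(ov$n_samples_a, 3L)

  ## two identical conspecific samples: intra = 1
  ov2 <- overlap_table(prof[1:2, ], meta[1:2, ], mode = "intra")
  expect_equal(ov2$pianka, 1)

  ## interspecific mean-diet mode
  meta3 <- tiny_metadata(c("S1", "S2", "S3"),
                         putative_species = c("moose", "moose", "red"))
  ovi <- overlap_table(prof, meta3, mode = "inter")
  expect_equal(ovi$kind, "inter")
  expect_equal(ovi$pianka, pianka(colMeans(m[1:2, ]), m[3, ]),
               tolerance = 1e-12)

  summ <- overlap_summary(ov)
  expect_true(summ$few_transects)  # single transect < 4
})

test_that("selectivity contrasts transect-average diets with availability", {
  cats <- c("pine", "birch")
  prof <- profile_from_matrix(rbind(S1 = c(pine = 0.3, birch = 0.7),
                                    S2 = c(pine = 0.3, birch = 0.7)))
  meta <- tiny_metadata(c("S1", "S2"), putative_species = "roe")
  av <- validate_table(data.frame(
    transect_id = "T01", season = "winter", height_range = "0-1.5m",
    category = cats, proportion = c(0.3, 0.7), stringsAsFactors = FALSE),
    "availability")
  sel <- selectivity_table(prof, av, meta)
  expect_equal(sel$records$D, c(0, 0))
  expect_true(all(sel$summary$mean_D == 0))
  expect_true(all(sel$summary$single_transect))

  ## category never eaten: D = -1; category eaten but unavailable: D = +1
  prof2 <- profile_from_matrix(rbind(S1 = c(pine = 0, birch = 0.8,
                                            juniper = 0.2)))
  av2 <- validate_table(data.frame(
    transect_id = "T01", season = "winter", height_range = "0-1.5m",
    category = c("pine", "birch"), proportion = c(0.4, 0.6),
    stringsAsFactors = FALSE), "availability")
  sel2 <- selectivity_table(prof2, av2, tiny_metadata("S1",
                                                      putative_species = "roe"))
  rec <- sel2$records
  expect_equal(rec$D[rec$category == "pine"], -1)
  expect_equal(rec$D[rec$category == "juniper"], 1)

  ## mean +/- SD across transects: {0.2, 0.4} -> 0.3 +/- 0.1414
  expect_equal(mean(c(0.2, 0.4)), 0.3)
  expect_equal(sd(c(0.2, 0.4)), 0.1414, tolerance = 1e-3)
})
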