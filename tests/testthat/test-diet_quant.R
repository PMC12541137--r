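test_that("replicate and sample distances match hand computations", {
  ## identical replicates: both PCR distances 0
  rc <- plant_counts_table(list(
    S1 = rbind(c(A = 50L, B = 50L), c(A = 50L, B = 50L)),
    S2 = rbind(c(A = 100L, B = 0L), c(A = 0L, B = 100L))))
  rd <- replicate_distances(rc)
  expect_equal(rd$pcr$distance[rd$pcr$sample_id == "S1"], c(0, 0))
  ## replicates (1,0) and (0,1): barycenter (0.5, 0.5), each BC distance 0.5
  expect_equal(rd$pcr$distance[rd$pcr$sample_id == "S2"], c(0.5, 0.5))
  ## two samples with identical barycenters: sample distance 0
  expect_equal(rd$sample_distances, 0)
})

test_that("qc_threshold is the 5th percentile of the fitted log-normal", {
  ## log-distances with sample mean exactly 0 and sd exactly 1
  set.seed(1)
  z <- as.numeric(scale(rnorm(200)))
  thr <- qc_threshold(exp(z))
  expect_equal(thr, exp(qnorm(0.05)), tolerance = 1e-10)
  expect_equal(thr, 0.1931, tolerance = 5e-4)

  ## degenerate: all distances equal d -> threshold d
  expect_equal(qc_threshold(rep(0.37, 25)), 0.37)

  ## too few distances: instructive error
  expect_error(qc_threshold(runif(5)), "explicit threshold")
})

test_that("replicate filtering applies depth, distance and control rules", {
  ## 999 reads is poor amplification; 1000 is not
  rep999 <- c(A = 399L, B = 400L, C = 200L)
  rep1000 <- c(A = 400L, B = 400L, C = 200L)
  mk <- function(tot) c(A = 0.4, B = 0.4, C = 0.2) * tot
  rc <- plant_counts_table(list(
    S1 = rbind(rep999, mk(5000), mk(5000)),
    S2 = rbind(rep1000, mk(5000))))
  out <- filter_replicates(rc, rc[0, ], threshold = 0.5)
  st <- out$report$status
  expect_equal(st[out$report$sample_id == "S1"][1], "discarded_low_reads")
  expect_true(all(st[out$report$sample_id == "S2"] == "kept"))

  ## three concordant replicates, one nudged past a tight threshold:
  ## that one is discarded, the sample survives with 2
  odd <- c(A = 0.1, B = 0.7, C = 0.2) * 5000
  rc2 <- plant_counts_table(list(S3 = rbind(mk(5000), mk(5000), odd)))
  out2 <- filter_replicates(rc2, rc2[0, ], threshold = 0.15)
  expect_equal(out2$report$status, c("kept", "kept", "discarded_distance"))
  expect_equal(nrow(out2$retained), 2)

  ## a replicate identical to the PCR-negative profile is control-like
  ctrl_prof <- c(A = 0L, B = 0L, C = 2000L)
  controls <- do.call(rbind, replicate(5, ctrl_prof, simplify = FALSE))
  rc3 <- plant_counts_table(
    list(S4 = rbind(mk(5000), mk(5000), ctrl_prof),
         S5 = rbind(mk(5000), mk(5000), mk(5000))),
    controls = controls)
  plant <- rc3[rc3$control_kind == "none", ]
  ctrl <- rc3[rc3$control_kind != "none", ]
  out3 <- filter_replicates(plant, ctrl, threshold = 2, k = 5)
  expect_equal(out3$report$status[out3$report$sample_id == "S4"],
               c("kept", "kept", "discarded_control_like"))

  ## a sample reduced below 2 kept replicates is dropped entirely
  rc4 <- plant_counts_table(list(S6 = rbind(c(A = 399L, B = 400L, C = 200L),
                                            c(A = 320L, B = 320L, C = 160L),
                                            mk(5000))))
  out4 <- filter_replicates(rc4, rc4[0, ], threshold = 0.5)
  expect_equal(nrow(out4$retained), 0)
  expect_true("S6" %in% out4$dropped_samples)
})

test_that("MOTU filters enforce similarity and sporadic-occurrence bounds", {
  catalog <- tiny_plant_catalog(c(A = 100, B = 94.9, C = 95, D = 100))
  ## sample S1: D at 2.6% once; sample S2: D at 0 -- D survives everywhere.
  ## In both, a MOTU capped at 2.4% max RRA must vanish.
  s1 <- c(A = 574L, B = 200L, C = 200L, D = 26L)  # D = 26/800 post-similarity
  s2 <- c(A = 800L, B = 0L, C = 176L, D = 24L)    # D = 2.4% after B drops
  rc <- plant_counts_table(list(S1 = rbind(s1, s1), S2 = rbind(s2, s2)))
  filt <- motu_filters(rc, catalog, min_max_rra = 0.025)
  expect_false("B" %in% names(filt))  # 94.9 < 95 removed
  expect_true(all(c("A", "C", "D") %in% names(filt)))

  ## with only S2, D's maximum RRA is 2.4% < 2.5%: sporadic, removed
  rc2 <- plant_counts_table(list(S2 = rbind(s2, s2)))
  filt2 <- motu_filters(rc2, catalog, min_max_rra = 0.025)
  expect_false("D" %in% names(filt2))

  ## renormalization: profile rows sum to 1 after removals
  prof <- to_rra(filt)
  expect_equal(unname(rowSums(profile_matrix(prof))), c(1, 1),
               tolerance = 1e-12)
})

test_that("to_rra converts counts to row proportions and drops empty rows", {
  x <- data.frame(sample_id = c("a", "b", "c"),
                  A = c(30, 1, 0), B = c(70, 0, 0))
  expect_warning(prof <- to_rra(x), "zero-total")
  expect_equal(nrow(prof), 2)
  expect_equal(unname(unlist(prof[1, c("A", "B")])), c(0.3, 0.7))
  expect_equal(unname(unlist(prof[2, c("A", "B")])), c(1, 0))
})

test_that("taxonomic collapsing is additive and commutes with RRA", {
  catalog <- validate_table(data.frame(
    motu_id = c("V1", "V2", "P1"), marker = "plant", length_bp = 48L,
    best_similarity = 100,
    taxonomy = c("Ericaceae;Vaccinium;Vaccinium myrtillus",
                 "Ericaceae;Vaccinium;Vaccinium vitis-idaea",
                 "Pinaceae;Pinus;Pinus sylvestris"),
    is_reference_exact = TRUE, stringsAsFactors = FALSE), "motu_catalog")
  prof <- profile_from_matrix(rbind(S1 = c(V1 = 0.10, V2 = 0.15, P1 = 0.75)))
  gen <- collapse_taxa(prof, catalog, rank = "genus")
  expect_equal(gen$Vaccinium, 0.25)
  expect_equal(gen$Pinus, 0.75)

  ## single-MOTU taxa unchanged; totals conserved
  fam <- collapse_taxa(prof, catalog, rank = "family")
  expect_equal(fam$Pinaceae, 0.75)
  expect_equal(rowSums(fam[, -1]), rowSums(prof[, -1]))

  ## family -> coarse categories equals direct member sums
  cmap <- c(Ericaceae = "shrubs", Pinaceae = "conifers")
  cats <- collapse_taxa(fam, rank = cmap)
  expect_equal(cats$shrubs, fam$Ericaceae)

  ## unmapped MOTU without fallback errors; fallback routes to 'other'
  expect_error(collapse_taxa(prof, rank = c(V1 = "x")), "no category")
  fb <- collapse_taxa(prof, rank = c(V1 = "x"), fallback = "other")
  expect_equal(fb$other, 0.90)

  ## commutativity: collapse counts then RRA == RRA then within-taxon sums
  counts <- data.frame(sample_id = "S1", V1 = 120, V2 = 80, P1 = 300)
  r1 <- to_rra(collapse_taxa(counts, catalog, rank = "genus"))
  r2 <- collapse_taxa(to_rra(counts), catalog, rank = "genus")
  expect_equal(profile_matrix(r1), profile_matrix(validate_table(
    r2, "diet_profile")), tolerance = 1e-12)
})

test_that("the filter pipeline is monotone and depth improves accuracy", {
  spec <- small_spec()
  sim <- simulate_dataset(spec, seed = 23)
  dq <- build_diet_profile(sim$read_counts, sim$motu_catalog)
  plant <- sim$read_counts[sim$read_counts$marker == "plant" &
                             sim$read_counts$control_kind == "none", ]
  ## no stage gains samples or MOTUs
  expect_lte(nrow(dq$profile), length(unique(plant$sample_id)))
  expect_lte(ncol(dq$profile) - 1, 210)

  ## RRA error against the latent truth shrinks with read depth
  mae <- function(depth_meanlog, seed) {
    sp <- small_spec(depth_meanlog = depth_meanlog, depth_sdlog = 0.1,
                     low_depth_rate = 0, control_like_rate = 0,
                     expected_samples = rbind(
                       coastal_boreal = c(moose = 2, roe = 0, red = 0,
                                          fallow = 0),
                       boreo_nemoral = c(moose = 2, roe = 0, red = 0,
                                         fallow = 0)))
    sm <- simulate_dataset(sp, seed = seed)
    d <- build_diet_profile(sm$read_counts, sm$motu_catalog,
                            min_max_rra = 0)
    m <- profile_matrix(d$profile)
    cols <- intersect(colnames(m), names(sm$truth))
    m <- m[, cols, drop = FALSE]
    tr <- as.matrix(sm$truth[match(rownames(m), sm$truth$sample_id), cols])
    mean(abs(m / rowSums(m) - tr / rowSums(tr)))
  }
  expect_lt(mae(log(1e5), 31), mae(log(1e3), 31))
})
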