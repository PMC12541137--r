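## Synthetic two-landscape cervid community generator.
##
## Emulates the sampling design the analysis assumes: 1x1 km square transects
## in a coastal-boreal (CB) and a boreo-nemoral (BN) landscape, four deer
## species, three seasons, three plant-marker PCR replicates per fecal sample
## plus extraction/PCR controls, a single mammal-marker PCR per sample,
## step-point forage availability on the diet transects, and pellet-group
## counts on the full transect grids.

cd_species  <- c("moose", "roe", "red", "fallow")
cd_seasons  <- c("spring", "summer_autumn", "winter")
cd_landscapes <- c("coastal_boreal", "boreo_nemoral")

cd_categories <- c("pine", "spruce", "juniper", "birch", "alder", "willow",
                   "poplar", "heather", "vaccinium", "other_ericaceous",
                   "forbs", "graminoids", "cereals", "other_browse", "other")

#' Latin binomial for each deer species code
#' @return Named character vector.
#' @export
cervid_latin <- function() {
  c(moose = "Alces alces", roe = "Capreolus capreolus",
    red = "Cervus elaphus", fallow = "Dama dama")
}

#' Browsing-height range surveyed for each deer species
#' @return Named character vector of height-range codes.
#' @export
species_height_range <- function() {
  c(moose = "0-3m", red = "0-2.3m", fallow = "0-1.8m", roe = "0-1.5m")
}

## -- taxon pool --------------------------------------------------------------

## 210 plant MOTUs across 77 family-level groups, each MOTU carrying a food
## category and a within-category rank (1 = most common member).
.build_taxon_pool <- function() {
  blocks <- list(
    list(cat = "pine",      fam = "Pinaceae",     gen = "Pinus",      n = 3),
    list(cat = "spruce",    fam = "Pinaceae",     gen = "Picea",      n = 2),
    list(cat = "juniper",   fam = "Cupressaceae", gen = "Juniperus",  n = 2),
    list(cat = "birch",     fam = "Betulaceae",   gen = "Betula",     n = 4),
    list(cat = "alder",     fam = "Betulaceae",   gen = "Alnus",      n = 2),
    list(cat = "willow",    fam = "Salicaceae",   gen = "Salix",      n = 6),
    list(cat = "poplar",    fam = "Salicaceae",   gen = "Populus",    n = 3),
    list(cat = "heather",   fam = "Ericaceae",    gen = "Calluna",    n = 2),
    list(cat = "vaccinium", fam = "Ericaceae",    gen = "Vaccinium",  n = 6),
    list(cat = "other_ericaceous", fam = "Ericaceae", gen = "Empetrum", n = 3),
    list(cat = "graminoids", fam = "Poaceae",     gen = "Avenella",   n = 5),
    list(cat = "graminoids", fam = "Poaceae",     gen = "Poa",        n = 5),
    list(cat = "graminoids", fam = "Juncaceae",   gen = "Luzula",     n = 6),
    list(cat = "graminoids", fam = "Cyperaceae",  gen = "Carex",      n = 5),
    list(cat = "cereals",   fam = "Poaceae",      gen = "Triticum",   n = 2),
    list(cat = "other_browse", fam = "Fagaceae",  gen = "Quercus",    n = 4),
    list(cat = "other_browse", fam = "Rosaceae",  gen = "Sorbus",     n = 6),
    list(cat = "forbs",     fam = "Fabaceae",     gen = "Trifolium",  n = 2),
    list(cat = "forbs",     fam = "Onagraceae",   gen = "Chamaenerion", n = 2),
    list(cat = "forbs",     fam = "Asteraceae",   gen = "Achillea",   n = 2))
  ## 33 further forb families x 2 MOTUs = 66, then filler families to reach
  ## 77 families / 210 MOTUs in the residual 'other' category.
  for (i in seq_len(32))
    blocks[[length(blocks) + 1L]] <-
      list(cat = "forbs", fam = sprintf("Forbfam%02d", i),
           gen = sprintf("Forbgen%02d", i), n = 2)
  for (i in seq_len(10))
    blocks[[length(blocks) + 1L]] <-
      list(cat = "other", fam = sprintf("Otherfam%02d", i),
           gen = sprintf("Othergen%02d", i), n = 3)
  for (i in 11:32)
    blocks[[length(blocks) + 1L]] <-
      list(cat = "other", fam = sprintf("Otherfam%02d", i),
           gen = sprintf("Othergen%02d", i), n = 2)
  pool <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(category = b$cat, family = b$fam, genus = b$gen,
               member = seq_len(b$n), stringsAsFactors = FALSE)
  }))
  ## within-category rank orders members across the category's genera so the
  ## first-ranked MOTUs sit in its leading genus
  pool <- pool[order(match(pool$category, cd_categories), pool$member), ]
  pool$cat_rank <- stats::ave(seq_len(nrow(pool)), pool$category,
                              FUN = seq_along)
  pool$motu_id <- sprintf("P%03d", seq_len(nrow(pool)))
  ## amplicon lengths typical of the P6-loop plant marker (10-220 bp, ~48 mean)
  set_len <- 20L + (seq_len(nrow(pool)) * 37L) %% 80L
  pool$length_bp <- set_len
  ## a handful of low-similarity artifact MOTUs in the residual category
  pool$best_similarity <- 100
  art <- which(pool$category == "other")[1:8]
  pool$best_similarity[art] <- c(85, 88, 90, 92, 93, 94, 94.5, 94.9)
  pool$best_similarity[pool$cat_rank > 1 & pool$category != "other"] <-
    rep(c(100, 98, 96.5), length.out = sum(pool$cat_rank > 1 &
                                             pool$category != "other"))
  pool$is_reference_exact <- pool$best_similarity == 100
  rownames(pool) <- NULL
  pool
}

## -- stratum diet means ------------------------------------------------------

## Category-level mean diets per species x season x landscape, parameterized
## from the reported landscape/seasonal contrasts (moose pine-dominated in
## winter/spring, graminoids essentially absent from moose, forbs and
## graminoids concentrated in the smaller deer, broad summer fallow diets).
.diet_category_means <- function() {
  d <- function(...) {
    v <- c(...)
    stopifnot(all(names(v) %in% cd_categories), sum(v) <= 1 + 1e-9)
    out <- stats::setNames(numeric(length(cd_categories)), cd_categories)
    out[names(v)] <- v
    out["other"] <- out["other"] + max(0, 1 - sum(v))
    out / sum(out)
  }
  A <- array(0, dim = c(4, 3, 2, length(cd_categories)),
             dimnames = list(cd_species, cd_seasons, cd_landscapes,
                             cd_categories))
  BN <- "boreo_nemoral"; CB <- "coastal_boreal"
  A["moose", "winter", BN, ] <- d(pine = .52, vaccinium = .24, juniper = .05,
    willow = .05, birch = .04, heather = .005, spruce = .02, forbs = .015,
    other_browse = .02, graminoids = .002, alder = .005, poplar = .01,
    other_ericaceous = .01)
  A["moose", "winter", CB, ] <- d(pine = .375, vaccinium = .33, juniper = .04,
    willow = .05, birch = .05, heather = .005, spruce = .01, forbs = .01,
    other_browse = .03, graminoids = .002, alder = .01, poplar = .01,
    other_ericaceous = .03)
  A["moose", "spring", BN, ] <- d(pine = .51, vaccinium = .25, juniper = .05,
    willow = .07, birch = .04, spruce = .01, forbs = .02, other_browse = .02,
    graminoids = .002, alder = .005, poplar = .01, other_ericaceous = .005)
  A["moose", "spring", CB, ] <- d(pine = .365, vaccinium = .33, juniper = .045,
    willow = .08, birch = .05, spruce = .005, forbs = .02, other_browse = .03,
    graminoids = .002, alder = .01, poplar = .015, other_ericaceous = .02)
  A["moose", "summer_autumn", BN, ] <- d(pine = .16, vaccinium = .30,
    birch = .20, willow = .12, forbs = .03, other_browse = .08, alder = .03,
    spruce = .01, juniper = .01, graminoids = .002, poplar = .02,
    heather = .005, other_ericaceous = .01)
  A["moose", "summer_autumn", CB, ] <- d(pine = .14, vaccinium = .38,
    birch = .18, willow = .10, forbs = .04, other_browse = .06, alder = .03,
    spruce = .005, juniper = .005, graminoids = .002, poplar = .02,
    heather = .005, other_ericaceous = .02)
  A["roe", "winter", BN, ] <- d(vaccinium = .42, heather = .09, birch = .07,
    willow = .04, graminoids = .09, forbs = .12, pine = .01, spruce = .015,
    juniper = .004, other_browse = .07, cereals = .005, alder = .01,
    poplar = .01, other_ericaceous = .03)
  A["roe", "winter", CB, ] <- d(vaccinium = .48, heather = .10, birch = .07,
    willow = .05, graminoids = .09, forbs = .04, pine = .005, spruce = .005,
    other_browse = .08, cereals = .002, alder = .01, poplar = .01,
    other_ericaceous = .04)
  A["roe", "spring", BN, ] <- d(vaccinium = .37, graminoids = .13,
    forbs = .16, heather = .08, birch = .07, willow = .04, other_browse = .07,
    pine = .01, spruce = .01, alder = .005, poplar = .01, cereals = .003,
    other_ericaceous = .02)
  A["roe", "spring", CB, ] <- d(vaccinium = .40, graminoids = .12,
    forbs = .12, heather = .08, birch = .08, willow = .05, other_browse = .07,
    pine = .005, spruce = .005, alder = .01, poplar = .01,
    other_ericaceous = .03)
  A["roe", "summer_autumn", BN, ] <- d(vaccinium = .20, birch = .17,
    forbs = .27, graminoids = .08, willow = .08, other_browse = .10,
    heather = .03, alder = .02, poplar = .02, spruce = .005,
    other_ericaceous = .02)
  A["roe", "summer_autumn", CB, ] <- d(vaccinium = .24, birch = .18,
    forbs = .22, graminoids = .08, willow = .08, other_browse = .09,
    heather = .03, alder = .02, poplar = .02, other_ericaceous = .02)
  A["red", "winter", BN, ] <- d(vaccinium = .32, heather = .10,
    graminoids = .13, forbs = .24, cereals = .01, birch = .05, pine = .02,
    spruce = .02, other_browse = .05, willow = .02, alder = .005,
    poplar = .005, other_ericaceous = .02)
  A["red", "winter", CB, ] <- d(vaccinium = .42, heather = .11,
    graminoids = .11, forbs = .09, cereals = .03, birch = .06, pine = .008,
    spruce = .01, other_browse = .06, willow = .03, alder = .01, poplar = .01,
    other_ericaceous = .03)
  A["red", "spring", BN, ] <- d(vaccinium = .33, heather = .09,
    graminoids = .14, forbs = .19, birch = .07, willow = .04, pine = .025,
    spruce = .015, other_browse = .05, cereals = .005, alder = .01,
    poplar = .01, other_ericaceous = .02)
  A["red", "spring", CB, ] <- d(vaccinium = .37, heather = .09,
    graminoids = .12, forbs = .13, birch = .09, willow = .05, pine = .008,
    spruce = .007, other_browse = .06, alder = .015, poplar = .01,
    other_ericaceous = .03)
  A["red", "summer_autumn", BN, ] <- d(birch = .20, vaccinium = .16,
    forbs = .23, graminoids = .12, willow = .06, other_browse = .08,
    heather = .03, spruce = .01, alder = .02, poplar = .02, pine = .01,
    other_ericaceous = .02)
  A["red", "summer_autumn", CB, ] <- d(birch = .33, vaccinium = .14,
    forbs = .19, graminoids = .09, willow = .06, other_browse = .07,
    heather = .03, alder = .02, poplar = .02, pine = .005,
    other_ericaceous = .02)
  A["fallow", "winter", BN, ] <- d(vaccinium = .28, forbs = .24,
    graminoids = .15, heather = .07, spruce = .05, cereals = .02, birch = .05,
    other_browse = .06, willow = .02, pine = .015, alder = .005,
    poplar = .005, other_ericaceous = .02)
  A["fallow", "winter", CB, ] <- d(vaccinium = .36, forbs = .12,
    graminoids = .14, heather = .08, spruce = .02, cereals = .02, birch = .06,
    other_browse = .08, willow = .03, pine = .005, alder = .01, poplar = .01,
    other_ericaceous = .04)
  A["fallow", "spring", BN, ] <- d(vaccinium = .26, graminoids = .19,
    forbs = .21, heather = .07, spruce = .04, birch = .06, willow = .04,
    other_browse = .07, pine = .015, cereals = .01, alder = .005,
    poplar = .005, other_ericaceous = .02)
  A["fallow", "spring", CB, ] <- d(vaccinium = .30, graminoids = .17,
    forbs = .17, heather = .07, spruce = .02, birch = .07, willow = .05,
    other_browse = .08, pine = .008, cereals = .005, alder = .01,
    poplar = .01, other_ericaceous = .03)
  fs <- d(forbs = .40, graminoids = .15, birch = .12, vaccinium = .10,
          willow = .06, other_browse = .08, spruce = .025, heather = .02,
          alder = .01, poplar = .01, pine = .005, other_ericaceous = .01)
  A["fallow", "summer_autumn", BN, ] <- fs
  A["fallow", "summer_autumn", CB, ] <- fs
  A
}

## Environment-side availability means per landscape category; height-range
## effect applied downstream (tree canopy enters taller browsing windows).
.availability_means <- function() {
  m <- rbind(
    coastal_boreal = c(pine = .22, spruce = .18, juniper = .02, birch = .15,
      alder = .02, willow = .04, poplar = .015, heather = .06,
      vaccinium = .17, other_ericaceous = .03, forbs = .04, graminoids = .08,
      cereals = .005, other_browse = .03, other = .02),
    boreo_nemoral = c(pine = .18, spruce = .16, juniper = .015, birch = .13,
      alder = .02, willow = .03, poplar = .015, heather = .05,
      vaccinium = .14, other_ericaceous = .02, forbs = .07, graminoids = .12,
      cereals = .03, other_browse = .05, other = .02))
  m[, cd_categories] / rowSums(m)
}

#' Default synthetic community specification
#'
#' Encodes the study conditions the generator emulates: two landscapes whose
#' deer density (cervid index, pellet groups per 100 m2), arable land and
#' habitat Shannon diversity contrast as in the field system (boreo-nemoral
#' 4.88 +/- 2.17, 15.7% +/- 14.4, H' 2.10 +/- 0.19; coastal-boreal
#' 0.43 +/- 0.62, 5.3% +/- 7.9, H' 1.95 +/- 0.17); a 210-MOTU plant taxon
#' pool in 77 family-level groups; species x season x landscape Dirichlet
#' mean diets with moose winter diets pine-dominated (> 50% boreo-nemoral,
#' 35-40% coastal-boreal) and graminoids essentially absent from moose;
#' a log-normal read-depth model; Dirichlet-multinomial replicate
#' overdispersion; and two replicate-failure mechanisms (low depth,
#' control-like composition).
#'
#' @return A list of class `"community_spec"`.
#' @export
make_default_spec <- function() {
  pool <- .build_taxon_pool()
  spec <- list(
    species = cd_species,
    seasons = cd_seasons,
    landscapes = cd_landscapes,
    n_diet_transects   = c(coastal_boreal = 17, boreo_nemoral = 16),
    n_pellet_transects = c(coastal_boreal = 76, boreo_nemoral = 50),
    ## expected fecal samples per diet transect x season
    expected_samples = rbind(
      coastal_boreal = c(moose = 2.5, roe = 1.2, red = 1.8, fallow = 0.25),
      boreo_nemoral  = c(moose = 2.5, roe = 1.2, red = 1.8, fallow = 1.5)),
    taxon_pool = pool,
    diet_means = .diet_category_means(),
    ## within-category geometric evenness: smaller decay = steeper dominance
    category_evenness = c(moose = 0.30, roe = 0.55, red = 0.60, fallow = 0.80),
    ## across-sample Dirichlet concentration per season: winter convergence on
    ## the few available resources, summer-autumn individual divergence
    diet_concentration = c(spring = 30, summer_autumn = 10, winter = 40),
    ## plant-marker read depth, log-normal
    depth_meanlog = log(8000), depth_sdlog = 0.5,
    ## replicate-level Dirichlet-multinomial overdispersion (0 disables)
    replicate_overdispersion = 200,
    ## replicate failure mechanisms
    low_depth_rate = 0.03, control_like_rate = 0.015,
    ## expected total reads per control kind (0 = clean control)
    contamination = c(extraction_blank = 150, pcr_negative = 60,
                      pcr_positive = 5000, primer_blank = 40),
    n_controls = c(extraction_blank = 8, pcr_negative = 4,
                   pcr_positive = 2, primer_blank = 10),
    ## mammal marker
    host_dominance = 0.95, mammal_depth_meanlog = log(4000),
    mammal_depth_sdlog = 0.5, mammal_low_depth_rate = 0.01,
    ## putative field species ID error
    misid_rate = 0.05, unknown_rate = 0.01,
    ## covariate distributions per landscape (cervid index gamma-matched)
    cervid_index_mean = c(coastal_boreal = 0.43, boreo_nemoral = 4.88),
    cervid_index_sd   = c(coastal_boreal = 0.62, boreo_nemoral = 2.17),
    arable_mean = c(coastal_boreal = 0.053, boreo_nemoral = 0.157),
    arable_sd   = c(coastal_boreal = 0.079, boreo_nemoral = 0.144),
    shannon_mean = c(coastal_boreal = 1.95, boreo_nemoral = 2.10),
    shannon_sd   = c(coastal_boreal = 0.17, boreo_nemoral = 0.19),
    large_class_share = 0.55,
    plot_missing_rate = 0.02,
    outlier_transect_rate = 0.015,
    availability_means = .availability_means(),
    availability_concentration = 150)
  class(spec) <- "community_spec"
  spec
}

#' Full MOTU-level Dirichlet mean diet for one stratum
#'
#' Expands the category-level mean diet to the 210-MOTU pool using the
#' species' within-category geometric evenness.
#'
#' @param spec A `community_spec`.
#' @param species,season,landscape Stratum identifiers.
#' @return Named numeric vector over the plant MOTU pool, summing to 1.
#' @export
stratum_mean_diet <- function(spec, species, season, landscape) {
  pool <- spec$taxon_pool
  catmeans <- spec$diet_means[species, season, landscape, ]
  r <- spec$category_evenness[[species]]
  w <- r ^ (pool$cat_rank - 1)
  wsum <- stats::ave(w, pool$category, FUN = sum)
  mu <- catmeans[pool$category] * w / wsum
  stats::setNames(as.numeric(mu / sum(mu)), pool$motu_id)
}

.validate_spec <- function(spec) {
  if (!inherits(spec, "community_spec")) stop("spec must be a community_spec")
  if (any(spec$diet_means < 0) ||
      any(abs(apply(spec$diet_means, 1:3, sum) - 1) > 1e-8))
    stop("invalid spec: Dirichlet category means must sum to 1 per stratum")
  rates <- c(spec$low_depth_rate, spec$control_like_rate, spec$contamination,
             spec$misid_rate, spec$unknown_rate, spec$mammal_low_depth_rate)
  if (any(rates < 0)) stop("invalid spec: all rates must be >= 0")
  invisible(spec)
}

## deterministic 32-bit child seed from a master seed and a stratum key
child_seed <- function(master, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 104729
  as.integer((as.numeric(master) * 7919 + h * 131) %% 2147483647)
}

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) { x <- as.numeric(alpha > 0) }
  x / sum(x)
}

## -- the generator -----------------------------------------------------------

#' Simulate a complete synthetic dataset
#'
#' Draws every pipeline input with the statistical structure the analysis
#' assumes. Per plant sample: a latent diet from the stratum Dirichlet;
#' three PCR replicates as multinomial draws of log-normal depth from a
#' replicate-level Dirichlet perturbation of the latent diet; a configurable
#' fraction of replicates fail by low depth or by control-like composition.
#' Mammal-marker PCRs carry a dominant host MOTU plus minor cross-species
#' reads and a short artifact MOTU. Controls draw from a contamination
#' profile. Pellet counts are drawn so the standardized cervid index matches
#' the landscape means of the spec. Identical `seed` gives identical output.
#'
#' @param spec A `community_spec`, see [make_default_spec()].
#' @param seed Integer master seed; per-stratum child seeds are derived
#'   deterministically from it.
#' @return A list with elements `read_counts`, `motu_catalog`,
#'   `sample_metadata`, `availability`, `pellet_counts`, `covariates`,
#'   `category_map` (MOTU to food category), and `truth` (latent per-sample
#'   diet proportions over the MOTU pool).
#' @export
simulate_dataset <- function(spec = make_default_spec(), seed = 1L) {
  .validate_spec(spec)
  pool <- spec$taxon_pool
  catalog <- .make_catalog(pool)
  plant_ids <- pool$motu_id
  mam <- catalog[catalog$marker == "mammal", ]
  host_motu <- stats::setNames(
    mam$motu_id[match(cervid_latin(), taxon_at_rank(mam$taxonomy, "species"))],
    names(cervid_latin()))
  all_ids <- catalog$motu_id
  contam_profile <- .contamination_profile(pool)

  meta_rows <- list(); truth_rows <- list(); count_rows <- list()
  sample_no <- 0L

  for (ls in spec$landscapes) {
    n_tr <- spec$n_diet_transects[[ls]]
    tr_ids <- sprintf("%s%02d", if (ls == "coastal_boreal") "CB" else "BN",
                      seq_len(n_tr))
    for (season in spec$seasons) {
      for (sp in spec$species) {
        set.seed(child_seed(seed, paste(ls, season, sp, "n")))
        n_per_tr <- stats::rpois(n_tr, spec$expected_samples[ls, sp])
        mu <- stratum_mean_diet(spec, sp, season, ls)
        conc <- spec$diet_concentration[[season]]
        set.seed(child_seed(seed, paste(ls, season, sp, "diet")))
        for (ti in seq_len(n_tr)) {
          for (k in seq_len(n_per_tr[ti])) {
            sample_no <- sample_no + 1L
            sid <- sprintf("S%04d", sample_no)
            latent <- .rdirichlet1(conc * mu)
            meta_rows[[sid]] <- data.frame(
              sample_id = sid, transect_id = tr_ids[ti], landscape = ls,
              season = season, collection_date = .random_date(season),
              putative_species = .putative(sp, spec),
              true_species = sp, stringsAsFactors = FALSE)
            truth_rows[[sid]] <- latent
            count_rows[[length(count_rows) + 1L]] <-
              .plant_replicates(sid, latent, spec, plant_ids, all_ids,
                                contam_profile)
            count_rows[[length(count_rows) + 1L]] <-
              .mammal_pcr(sid, sp, spec, host_motu, mam, all_ids)
          }
        }
      }
    }
  }

  set.seed(child_seed(seed, "controls"))
  count_rows[[length(count_rows) + 1L]] <- .controls(spec, pool, all_ids)

  rc <- do.call(rbind, count_rows)
  rc <- validate_table(rc, "read_counts")

  meta <- do.call(rbind, meta_rows)
  truth_mat <- do.call(rbind, truth_rows)
  colnames(truth_mat) <- plant_ids
  truth <- data.frame(sample_id = meta$sample_id,
                      as.data.frame(truth_mat, row.names = NULL),
                      check.names = FALSE)
  true_species <- meta$true_species
  meta$true_species <- NULL
  meta <- validate_table(meta, "sample_metadata")
  truth$true_species <- true_species

  avail <- .make_availability(spec, seed)
  pellets <- .make_pellets(spec, seed)
  covar <- .make_covariates(spec, seed, pellets)

  list(read_counts = rc, motu_catalog = catalog, sample_metadata = meta,
       availability = avail, pellet_counts = pellets, covariates = covar,
       category_map = stats::setNames(pool$category, pool$motu_id),
       truth = truth)
}

.make_catalog <- function(pool) {
  plant <- data.frame(
    motu_id = pool$motu_id, marker = "plant", length_bp = pool$length_bp,
    best_similarity = pool$best_similarity,
    taxonomy = paste(pool$family, pool$genus,
                     paste(pool$genus, tolower(pool$motu_id)), sep = ";"),
    is_reference_exact = pool$is_reference_exact, stringsAsFactors = FALSE)
  latin <- cervid_latin()
  mammal <- data.frame(
    motu_id = c(sprintf("M%02d", seq_along(latin)), "M90", "M91", "M92"),
    marker = "mammal",
    length_bp = c(72L, 68L, 70L, 74L, 39L, 66L, 71L),
    best_similarity = c(100, 100, 100, 100, 60, 88, 100),
    taxonomy = c(paste("Cervidae", vapply(strsplit(latin, " "), `[`, "",
                                          1L), latin, sep = ";"),
                 "unassigned", "Suidae;Sus;Sus scrofa",
                 "Ursidae;Ursus;Ursus arctos"),
    is_reference_exact = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  positive <- data.frame(
    motu_id = "PPOS", marker = "plant", length_bp = 55L,
    best_similarity = 100,
    taxonomy = "Apocynaceae;Stephanotis;Stephanotis floribunda",
    is_reference_exact = TRUE, stringsAsFactors = FALSE)
  validate_table(rbind(plant, positive, mammal), "motu_catalog")
}

.random_date <- function(season) {
  mo <- switch(season,
               spring = sample(4:5, 1),
               summer_autumn = sample(6:10, 1),
               winter = sample(c(11, 12, 1, 2, 3), 1))
  yr <- if (mo <= 3) 2017 else 2016
  sprintf("%d-%02d-%02d", yr, mo, sample(1:28, 1))
}

.putative <- function(sp, spec) {
  u <- stats::runif(1)
  if (u < spec$unknown_rate) return("unknown")
  if (u < spec$unknown_rate + spec$misid_rate)
    return(sample(setdiff(cd_species, sp), 1))
  sp
}

.count_row <- function(pcr_id, sample_id, marker, rep_idx, control_kind,
                       counts, all_ids) {
  full <- stats::setNames(integer(length(all_ids)), all_ids)
  full[names(counts)] <- as.integer(counts)
  out <- data.frame(pcr_id = pcr_id, sample_id = sample_id, marker = marker,
                    replicate_index = rep_idx, control_kind = control_kind,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(t(full), check.names = FALSE))
}

.contamination_profile <- function(pool) {
  ## ubiquitous taxa dominate cross-contamination and tag jumps
  lead <- pool$motu_id[pool$cat_rank == 1 &
                         pool$category %in% c("vaccinium", "birch", "pine",
                                              "graminoids", "forbs")]
  p <- stats::setNames(rep(1 / length(lead), length(lead)), lead)
  p
}

.plant_replicates <- function(sid, latent, spec, plant_ids, all_ids, contam) {
  rows <- vector("list", 3L)
  for (r in 1:3) {
    depth <- round(stats::rlnorm(1, spec$depth_meanlog, spec$depth_sdlog))
    comp <- latent
    if (spec$replicate_overdispersion > 0)
      comp <- .rdirichlet1(spec$replicate_overdispersion * latent)
    names(comp) <- plant_ids
    u <- stats::runif(1)
    if (u < spec$low_depth_rate) {
      depth <- sample(100:999, 1)
    } else if (u < spec$low_depth_rate + spec$control_like_rate) {
      comp <- 0.05 * comp
      comp[names(contam)] <- comp[names(contam)] + 0.95 * contam
      comp <- comp / sum(comp)
    }
    counts <- stats::rmultinom(1, size = max(depth, 1), prob = comp)[, 1]
    names(counts) <- plant_ids
    rows[[r]] <- .count_row(sprintf("%s-P%d", sid, r), sid, "plant", r,
                            "none", counts, all_ids)
  }
  do.call(rbind, rows)
}

.mammal_pcr <- function(sid, sp, spec, host_motu, mam, all_ids) {
  depth <- round(stats::rlnorm(1, spec$mammal_depth_meanlog,
                               spec$mammal_depth_sdlog))
  if (stats::runif(1) < spec$mammal_low_depth_rate)
    depth <- sample(50:450, 1)
  others <- host_motu[setdiff(names(host_motu), sp)]
  p <- stats::setNames(numeric(0), character(0))
  p[host_motu[[sp]]] <- spec$host_dominance
  p[others] <- (1 - spec$host_dominance - 0.012) *
    .rdirichlet1(rep(1, length(others)))
  p["M90"] <- 0.008  # short bacterial artifact
  p["M91"] <- 0.004  # non-reference mammal trace
  counts <- stats::rmultinom(1, size = max(depth, 1), prob = p / sum(p))[, 1]
  names(counts) <- names(p)
  .count_row(sprintf("%s-M1", sid), sid, "mammal", 1L, "none", counts, all_ids)
}

.controls <- function(spec, pool, all_ids) {
  contam <- .contamination_profile(pool)
  rows <- list()
  for (kind in names(spec$n_controls)) {
    lambda <- spec$contamination[[kind]]
    for (i in seq_len(spec$n_controls[[kind]])) {
      depth <- stats::rpois(1, lambda)
      prob <- contam
      if (kind == "pcr_positive") {
        prob <- c(stats::setNames(0.985, "PPOS"), 0.015 * contam)
      }
      counts <- if (depth > 0)
        stats::rmultinom(1, depth, prob / sum(prob))[, 1]
      else stats::setNames(integer(length(prob)), names(prob))
      names(counts) <- names(prob)
      rows[[length(rows) + 1L]] <- .count_row(
        sprintf("CTRL-%s-%02d", kind, i), NA_character_, "plant", i, kind,
        counts, all_ids)
    }
  }
  do.call(rbind, rows)
}

.make_availability <- function(spec, seed) {
  heights <- cd_enums$height_range
  hfac <- c("0-1.5m" = 1.5, "0-1.8m" = 1.8, "0-2.3m" = 2.3, "0-3m" = 3.0)
  tree <- c("pine", "spruce", "juniper", "birch", "alder", "willow", "poplar",
            "other_browse")
  rows <- list()
  for (ls in spec$landscapes) {
    base <- spec$availability_means[ls, ]
    n_tr <- spec$n_diet_transects[[ls]]
    tr_ids <- sprintf("%s%02d", if (ls == "coastal_boreal") "CB" else "BN",
                      seq_len(n_tr))
    set.seed(child_seed(seed, paste(ls, "avail")))
    for (tid in tr_ids) for (season in spec$seasons) for (h in heights) {
      m <- base
      m[tree] <- m[tree] * hfac[[h]] / 3.0  # canopy enters taller windows
      m <- m / sum(m)
      p <- .rdirichlet1(spec$availability_concentration * m)
      rows[[length(rows) + 1L]] <- data.frame(
        transect_id = tid, season = season, height_range = h,
        category = cd_categories, proportion = p, stringsAsFactors = FALSE)
    }
  }
  validate_table(do.call(rbind, rows), "availability")
}

.make_pellets <- function(spec, seed) {
  rows <- list()
  for (ls in spec$landscapes) {
    n_tr <- spec$n_pellet_transects[[ls]]
    tr_ids <- sprintf("%s%02d", if (ls == "coastal_boreal") "CB" else "BN",
                      seq_len(n_tr))
    m <- spec$cervid_index_mean[[ls]]; s <- spec$cervid_index_sd[[ls]]
    shape <- (m / s)^2; rate <- m / s^2
    set.seed(child_seed(seed, paste(ls, "pellets")))
    lam <- stats::rgamma(n_tr, shape = shape, rate = rate)
    outlier <- stats::runif(n_tr) < spec$outlier_transect_rate
    lam[outlier] <- stats::runif(sum(outlier), 26, 35)
    small_area <- if (ls == "boreo_nemoral") 10 else 100
    for (ti in seq_len(n_tr)) {
      surveyed <- stats::runif(16) > spec$plot_missing_rate
      if (ti == n_tr) surveyed[1:5] <- FALSE  # one under-surveyed transect
      lam_l <- lam[ti] * spec$large_class_share
      lam_s <- lam[ti] * (1 - spec$large_class_share)
      for (pl in 1:16) {
        nl <- if (surveyed[pl]) stats::rpois(1, lam_l * 100 / 100) else 0L
        ns <- if (surveyed[pl]) stats::rpois(1, lam_s * small_area / 100)
              else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          transect_id = tr_ids[ti], year = 2016L, plot_id = pl,
          plot_area_m2 = c(100, small_area), species_class = c("large",
                                                               "small"),
          pellet_groups = c(nl, ns), surveyed = surveyed[pl],
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_table(do.call(rbind, rows), "pellet_counts")
}

.make_covariates <- function(spec, seed, pellets) {
  ci <- cervid_index(pellets)
  rows <- list()
  for (ls in spec$landscapes) {
    pre <- if (ls == "coastal_boreal") "CB" else "BN"
    tr <- ci$transect_id[startsWith(ci$transect_id, pre)]
    set.seed(child_seed(seed, paste(ls, "covar")))
    m <- spec$arable_mean[[ls]]; v <- spec$arable_sd[[ls]]^2
    phi <- m * (1 - m) / v - 1
    arable <- stats::rbeta(length(tr), m * phi, (1 - m) * phi)
    shan <- pmax(0, stats::rnorm(length(tr), spec$shannon_mean[[ls]],
                                 spec$shannon_sd[[ls]]))
    rows[[length(rows) + 1L]] <- data.frame(
      transect_id = tr,
      cervid_index = ci$cervid_index[match(tr, ci$transect_id)],
      habitat_shannon = shan, arable_prop = arable, stringsAsFactors = FALSE)
  }
  validate_table(do.call(rbind, rows), "covariates")
}
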