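## Diet richness, dietary niche width, Pianka overlap, Jacob's selectivity.

#' Per-sample diet richness
#'
#' Richness S is the number of taxa with strictly positive RRA in a sample,
#' counted on the post-QC MOTU-level profile (after the sporadic-occurrence
#' filter, before category collapsing).
#'
#' @param profile A `diet_profile` table.
#' @param metadata A `sample_metadata` table; assignments joined on
#'   `sample_id`.
#' @param species Optional vector of host species per profile row (e.g., from
#'   [host_assignments()]); falls back to `putative_species` in the metadata.
#' @return Data frame `sample_id`, `species`, `landscape`, `season`, `S`.
#' @export
richness <- function(profile, metadata, species = NULL) {
  m <- profile_matrix(profile)
  S <- rowSums(m > 0)
  i <- match(profile$sample_id, metadata$sample_id)
  sp <- if (is.null(species)) metadata$putative_species[i] else species
  data.frame(sample_id = profile$sample_id, species = sp,
             landscape = metadata$landscape[i], season = metadata$season[i],
             S = as.integer(S), stringsAsFactors = FALSE)
}

#' Pairwise Dunn rank-sum tests with Benjamini-Hochberg adjustment
#'
#' Ranks all values jointly with mid-rank ties; for each group pair
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T)(1/ni + 1/nj))` where the tie
#' correction is `T = sum(t^3 - t) / (12 (N - 1))` over tie groups of size
#' `t`. Two-sided p-values come from the standard normal; the BH step-up
#' adjustment is applied over all pairs.
#'
#' @param values Numeric vector (e.g., per-sample richness).
#' @param groups Group labels, same length.
#' @return Data frame `group_a`, `group_b`, `z`, `p`, `p_adj`.
#' @export
dunn_bh <- function(values, groups) {
  groups <- as.character(groups)
  n_by <- table(groups)
  small <- names(n_by)[n_by < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    n_by <- table(groups)
  }
  if (length(n_by) < 2) stop("need at least 2 groups with >= 2 observations")
  N <- length(values)
  r <- rank(values)  # mid-ranks
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  gn <- sort(names(n_by))
  pairs <- utils::combn(gn, 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) *
                 (1 / n_by[[i]] + 1 / n_by[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  res <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    z = out["z", ], p = out["p", ],
                    stringsAsFactors = FALSE, row.names = NULL)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Dietary niche width: exponential Shannon index of the average diet
#'
#' The population average diet is the unweighted arithmetic mean of the
#' sample RRA vectors (renormalized); `DNW = exp(H')` with
#' `H' = -sum(q log q)` over its positive entries -- the effective number of
#' food taxa used (Hill number of order 1). DNW is 1 for a single-taxon diet
#' and equals the taxon count for a uniform one.
#'
#' @param profile A `diet_profile` table (one stratum's rows).
#' @return Single number >= 1.
#' @export
dnw <- function(profile) {
  m <- profile_matrix(profile)
  if (!nrow(m)) stop("empty stratum: no samples")
  q <- colMeans(m)
  q <- q / sum(q)
  q <- q[q > 0]
  exp(-sum(q * log(q)))
}

#' DNW per landscape x species x season stratum
#'
#' @param profile A `diet_profile` table.
#' @param metadata A `sample_metadata` table.
#' @param species Host species per profile row (defaults to
#'   `putative_species`).
#' @return Data frame `landscape`, `season`, `species`, `n_samples`, `dnw`.
#' @export
dnw_table <- function(profile, metadata, species = NULL) {
  i <- match(profile$sample_id, metadata$sample_id)
  sp <- if (is.null(species)) metadata$putative_species[i] else species
  key <- data.frame(landscape = metadata$landscape[i],
                    season = metadata$season[i], species = sp,
                    stringsAsFactors = FALSE)
  grp <- interaction(key$landscape, key$season, key$species, drop = TRUE)
  out <- lapply(levels(grp), function(g) {
    rows <- which(grp == g)
    cbind(key[rows[1], , drop = FALSE],
          data.frame(n_samples = length(rows),
                     dnw = dnw(profile[rows, , drop = FALSE])))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pianka's niche overlap index
#'
#' `O = sum(u v) / sqrt(sum(u^2) sum(v^2))`: 0 = no overlap (disjoint
#' resource use), 1 = complete overlap (identical use). Symmetric and in
#' \[0,1\] by Cauchy-Schwarz.
#'
#' @param u,v Resource-use proportion vectors over the same taxon columns.
#' @return Overlap in \[0,1\].
#' @export
pianka <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have the same length")
  su <- sum(u^2); sv <- sum(v^2)
  if (su == 0 || sv == 0) stop("Pianka's index undefined for a zero vector")
  min(1, sum(u * v) / sqrt(su * sv))
}

#' Jacob's selectivity index
#'
#' `D = (r - p) / (r + p - 2 r p)` where `r` is the dietary proportion of a
#' food item and `p` its relative environmental availability. Ranges from -1
#' (complete avoidance) through 0 (neutral) to +1 (exclusive preference).
#' Undefined where the denominator vanishes (r = p = 0 or r = p = 1).
#'
#' @param r Diet proportion(s) in \[0,1\].
#' @param p Availability proportion(s) in \[0,1\].
#' @return Numeric vector in \[-1,1\]; `NA` where undefined.
#' @export
jacobs_d <- function(r, p) {
  den <- r + p - 2 * r * p
  out <- ifelse(abs(den) < .Machine$double.eps * 4, NA_real_, (r - p) / den)
  out
}

#' Transect-scale Pianka overlap table
#'
#' Intraspecific mode: for each transect x season x species with at least two
#' samples, the mean Pianka index over all unordered sample pairs.
#' Interspecific mode: for each transect x season x heterospecific pair with
#' at least one sample each, the Pianka index between the two species' mean
#' diets on that transect (`inter_mode = "pairs"` averages over
#' heterospecific sample pairs instead).
#'
#' @param profile A `diet_profile` table.
#' @param metadata A `sample_metadata` table.
#' @param species Host species per profile row (defaults to
#'   `putative_species`).
#' @param mode `"intra"`, `"inter"`, or `"both"` (default).
#' @param inter_mode `"mean_diet"` (default) or `"pairs"`.
#' @return A validated `overlap` table.
#' @export
overlap_table <- function(profile, metadata, species = NULL,
                          mode = c("both", "intra", "inter"),
                          inter_mode = c("mean_diet", "pairs")) {
  mode <- match.arg(mode); inter_mode <- match.arg(inter_mode)
  m <- profile_matrix(profile)
  i <- match(profile$sample_id, metadata$sample_id)
  sp <- if (is.null(species)) metadata$putative_species[i] else species
  info <- data.frame(transect_id = metadata$transect_id[i],
                     landscape = metadata$landscape[i],
                     season = metadata$season[i], species = sp,
                     stringsAsFactors = FALSE)
  keep <- info$species %in% cd_enums$species
  m <- m[keep, , drop = FALSE]; info <- info[keep, , drop = FALSE]
  rows <- list()
  for (ts in unique(paste(info$transect_id, info$season))) {
    idx <- which(paste(info$transect_id, info$season) == ts)
    tr <- info$transect_id[idx[1]]; se <- info$season[idx[1]]
    ls <- info$landscape[idx[1]]
    spp <- info$species[idx]
    if (mode != "inter") for (s in unique(spp)) {
      j <- idx[spp == s]
      if (length(j) < 2) next
      prs <- utils::combn(j, 2)
      ov <- mean(apply(prs, 2, function(pr) pianka(m[pr[1], ], m[pr[2], ])))
      rows[[length(rows) + 1L]] <- data.frame(
        transect_id = tr, season = se, landscape = ls, kind = "intra",
        species_a = s, species_b = s, pianka = ov,
        n_samples_a = length(j), n_samples_b = length(j),
        stringsAsFactors = FALSE)
    }
    if (mode != "intra") {
      us <- sort(unique(spp))
      if (length(us) >= 2) for (pr in utils::combn(us, 2, simplify = FALSE)) {
        ja <- idx[spp == pr[1]]; jb <- idx[spp == pr[2]]
        ov <- if (inter_mode == "mean_diet") {
          pianka(colMeans(m[ja, , drop = FALSE]),
                 colMeans(m[jb, , drop = FALSE]))
        } else {
          mean(outer(ja, jb, Vectorize(function(a, b)
            pianka(m[a, ], m[b, ]))))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          transect_id = tr, season = se, landscape = ls, kind = "inter",
          species_a = pr[1], species_b = pr[2], pianka = ov,
          n_samples_a = length(ja), n_samples_b = length(jb),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(validate_table(data.frame(transect_id = character(),
      season = character(), landscape = character(), kind = character(),
      species_a = character(), species_b = character(), pianka = numeric(),
      n_samples_a = integer(), n_samples_b = integer()), "overlap"))
  validate_table(do.call(rbind, rows), "overlap")
}

#' Landscape x season summaries of transect-scale overlap
#'
#' Mean and SD across transects, with a flag for cells resting on fewer than
#' 4 transects (interpret with caution).
#'
#' @param overlaps An `overlap` table from [overlap_table()].
#' @return Data frame with `landscape`, `season`, `kind`, `species_a`,
#'   `species_b`, `mean`, `sd`, `n_transects`, `few_transects`.
#' @export
overlap_summary <- function(overlaps) {
  key <- paste(overlaps$landscape, overlaps$season, overlaps$kind,
               overlaps$species_a, overlaps$species_b, sep = "|")
  out <- lapply(unique(key), function(k) {
    rows <- overlaps[key == k, , drop = FALSE]
    data.frame(landscape = rows$landscape[1], season = rows$season[1],
               kind = rows$kind[1], species_a = rows$species_a[1],
               species_b = rows$species_b[1], mean = mean(rows$pianka),
               sd = if (nrow(rows) > 1) stats::sd(rows$pianka) else NA_real_,
               n_transects = nrow(rows),
               few_transects = nrow(rows) < 4, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Jacob's D selectivity table against step-point availability
#'
#' For each transect x season x species x food category: `r` is the
#' transect-average diet proportion of the category (mean over that species'
#' samples on the transect), `p` the availability proportion for the
#' species' browsing-height range on that transect and season. Categories
#' absent from the availability table get `p = 0` (so `D = 1` when eaten).
#'
#' @param profile A `diet_profile` collapsed to the availability category
#'   set (see [collapse_taxa()]).
#' @param availability An `availability` table.
#' @param metadata A `sample_metadata` table.
#' @param species Host species per profile row (defaults to
#'   `putative_species`).
#' @return List: `records` (per transect x season x species x category rows
#'   with `r`, `p`, `D`) and `summary` (per landscape x season x species x
#'   category mean and SD across transects; single-transect strata have
#'   `sd = NA` and are flagged).
#' @export
selectivity_table <- function(profile, availability, metadata,
                              species = NULL) {
  m <- profile_matrix(profile)
  i <- match(profile$sample_id, metadata$sample_id)
  sp <- if (is.null(species)) metadata$putative_species[i] else species
  hr <- species_height_range()
  keep <- sp %in% names(hr)
  m <- m[keep, , drop = FALSE]
  info <- data.frame(transect_id = metadata$transect_id[i][keep],
                     landscape = metadata$landscape[i][keep],
                     season = metadata$season[i][keep], species = sp[keep],
                     stringsAsFactors = FALSE)
  cats <- colnames(m)
  rows <- list()
  grp <- paste(info$transect_id, info$season, info$species)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    tr <- info$transect_id[idx[1]]; se <- info$season[idx[1]]
    s <- info$species[idx[1]]
    av <- availability[availability$transect_id == tr &
                         availability$season == se &
                         availability$height_range == hr[[s]], , drop = FALSE]
    if (!nrow(av)) next
    p <- stats::setNames(av$proportion, av$category)[cats]
    p[is.na(p)] <- 0
    r <- colMeans(m[idx, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      transect_id = tr, season = se, landscape = info$landscape[idx[1]],
      species = s, category = cats, r = as.numeric(r), p = as.numeric(p),
      D = jacobs_d(as.numeric(r), as.numeric(p)),
      n_samples = length(idx), stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  skey <- paste(records$landscape, records$season, records$species,
                records$category, sep = "|")
  summ <- lapply(unique(skey), function(k) {
    rr <- records[skey == k & !is.na(records$D), , drop = FALSE]
    if (!nrow(rr)) return(NULL)
    data.frame(landscape = rr$landscape[1], season = rr$season[1],
               species = rr$species[1], category = rr$category[1],
               mean_D = mean(rr$D),
               sd_D = if (nrow(rr) > 1) stats::sd(rr$D) else NA_real_,
               n_transects = nrow(rr), single_transect = nrow(rr) < 2,
               stringsAsFactors = FALSE)
  })
  list(records = records, summary = do.call(rbind, summ))
}
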