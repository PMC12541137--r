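## Plant-marker replicate QC, MOTU filtering, taxonomic collapsing and
## RRA diet-profile construction.

## compositional distance between two proportion vectors
.comp_dist <- function(x, y, method = c("bray", "hellinger")) {
  method <- match.arg(method)
  if (method == "bray") sum(abs(x - y)) / sum(x + y)
  else sqrt(sum((sqrt(x) - sqrt(y))^2))
}

.row_props <- function(m) {
  tot <- rowSums(m)
  sweep(m, 1, ifelse(tot > 0, tot, 1), "/")
}

#' Replicate and sample compositional distances
#'
#' Converts each plant-marker PCR to within-PCR proportions, computes per
#' sample the barycenter (arithmetic mean of its replicate proportion
#' vectors), each replicate's distance to its own barycenter (PCR distances),
#' and all pairwise distances between barycenters (sample distances). Under
#' ideal amplification PCR distances are near zero relative to sample
#' distances; the contrast drives the QC threshold.
#'
#' @param rc A `read_counts` table of plant-marker, non-control PCRs.
#' @param method Compositional distance: `"bray"` (Bray-Curtis on
#'   proportions, default) or `"hellinger"` (Euclidean on square-root
#'   proportions).
#' @return List: `pcr` (data frame `sample_id`, `pcr_id`, `replicate_index`,
#'   `distance`), `sample_distances` (numeric vector over unordered sample
#'   pairs), `barycenters` (matrix, one row per sample), `flagged` (samples
#'   with fewer than 2 replicates, excluded from threshold estimation).
#' @export
replicate_distances <- function(rc, method = c("bray", "hellinger")) {
  method <- match.arg(method)
  rc <- rc[rc$marker == "plant" & rc$control_kind == "none", , drop = FALSE]
  m <- .row_props(count_matrix(rc))
  sid <- rc$sample_id
  samples <- unique(sid)
  nrep <- table(sid)
  flagged <- names(nrep)[nrep < 2]
  bary <- t(vapply(samples, function(s)
    colMeans(m[sid == s, , drop = FALSE]), numeric(ncol(m))))
  rownames(bary) <- samples
  pcr <- data.frame(
    sample_id = sid, pcr_id = rc$pcr_id,
    replicate_index = rc$replicate_index,
    distance = vapply(seq_len(nrow(m)), function(i)
      .comp_dist(m[i, ], bary[sid[i], ], method), numeric(1)),
    stringsAsFactors = FALSE)
  ok <- setdiff(samples, flagged)
  sdist <- numeric(0)
  if (length(ok) >= 2) {
    d <- if (method == "bray") vegan::vegdist(bary[ok, , drop = FALSE],
                                              method = "bray")
         else stats::dist(sqrt(bary[ok, , drop = FALSE]))
    sdist <- as.numeric(d)
  }
  list(pcr = pcr, sample_distances = sdist, barycenters = bary,
       flagged = flagged)
}

#' Replicate-consistency quality threshold
#'
#' Fits a normal distribution to the log of the between-sample barycenter
#' distances and returns its 5th percentile on the natural scale,
#' `exp(mu + qnorm(0.05) * sigma)`. Replicates whose distance to their own
#' barycenter exceeds this value are inconsistent with the bulk of
#' between-sample variation and are discarded as outliers.
#'
#' @param sample_distances Positive sample (between-barycenter) distances.
#' @param prob Quantile used (default 0.05).
#' @param min_n Minimum number of positive distances required (default 20).
#' @return The threshold (single positive number).
#' @export
qc_threshold <- function(sample_distances, prob = 0.05, min_n = 20) {
  d <- sample_distances[is.finite(sample_distances) & sample_distances > 0]
  if (length(d) < min_n)
    stop("only ", length(d), " positive sample distances (need >= ", min_n,
         "); supply an explicit threshold instead")
  ld <- log(d)
  mu <- mean(ld)
  sigma <- if (length(ld) > 1) stats::sd(ld) else 0
  if (!is.finite(sigma)) sigma <- 0
  exp(mu + stats::qnorm(prob) * sigma)
}

#' Filter plant PCR replicates
#'
#' Applies the three discard rules in fixed order: (1) poor amplification,
#' total reads < `min_reads`; (2) distance to the sample barycenter above
#' `threshold` (barycenters recomputed after rule 1); (3) clustering with
#' controls, decided by a deterministic k-nearest-neighbour rule over the
#' composition vectors of all surviving replicates plus non-empty controls --
#' a replicate whose majority of `k` nearest neighbours are controls is
#' discarded. Samples left with fewer than 2 kept replicates are dropped.
#'
#' @param rc A `read_counts` table of plant-marker non-control PCRs.
#' @param controls A `read_counts` table of control rows (any marker;
#'   zero-read controls are ignored for the k-NN rule).
#' @param threshold Distance threshold from [qc_threshold()].
#' @param min_reads Minimum replicate total (default 1000; 999 is discarded).
#' @param k Neighbourhood size for the control rule (default 5).
#' @param method Compositional distance, as in [replicate_distances()].
#' @return List: `report` (per-replicate `sample_id`, `replicate_index`,
#'   `status`, `distance_to_barycenter`, `threshold_used`) and `retained`
#'   (the surviving rows of `rc`).
#' @export
filter_replicates <- function(rc, controls, threshold, min_reads = 1000,
                              k = 5, method = c("bray", "hellinger")) {
  method <- match.arg(method)
  rc <- rc[rc$marker == "plant" & rc$control_kind == "none", , drop = FALSE]
  m <- count_matrix(rc)
  status <- rep("kept", nrow(rc))
  dist_b <- rep(NA_real_, nrow(rc))

  ## rule 1: poor amplification
  status[rowSums(m) < min_reads] <- "discarded_low_reads"

  ## rule 2: barycenter-distance outliers among surviving replicates
  alive <- status == "kept"
  if (any(alive)) {
    sub <- rc[alive, , drop = FALSE]
    props <- .row_props(m[alive, , drop = FALSE])
    for (s in unique(sub$sample_id)) {
      i <- which(sub$sample_id == s)
      if (length(i) < 2) next
      b <- colMeans(props[i, , drop = FALSE])
      dd <- vapply(i, function(j) .comp_dist(props[j, ], b, method),
                   numeric(1))
      dist_b[which(alive)[i]] <- dd
      out <- dd > threshold
      status[which(alive)[i][out]] <- "discarded_distance"
    }
  }

  ## rule 3: control-likeness by k-NN majority
  alive <- status == "kept"
  ctrl <- controls[rowSums(count_matrix(controls)) > 0, , drop = FALSE]
  if (any(alive) && nrow(ctrl) > 0) {
    rep_p <- .row_props(count_matrix(rc[alive, , drop = FALSE]))
    shared <- intersect(colnames(rep_p), colnames(count_matrix(ctrl)))
    ctrl_p <- .row_props(count_matrix(ctrl))[, shared, drop = FALSE]
    all_p <- rbind(rep_p[, shared, drop = FALSE], ctrl_p)
    is_ctrl <- c(rep(FALSE, nrow(rep_p)), rep(TRUE, nrow(ctrl_p)))
    d <- as.matrix(if (method == "bray") vegan::vegdist(all_p, "bray")
                   else stats::dist(sqrt(all_p)))
    kk <- min(k, nrow(all_p) - 1L)
    for (i in seq_len(nrow(rep_p))) {
      nb <- order(d[i, -i])[seq_len(kk)]
      nb_ctrl <- is_ctrl[-i][nb]
      if (sum(nb_ctrl) > kk / 2)
        status[which(alive)[i]] <- "discarded_control_like"
    }
  }

  ## drop samples with < 2 kept replicates
  keep_tab <- table(rc$sample_id[status == "kept"])
  lonely <- names(keep_tab)[keep_tab < 2]
  report <- data.frame(sample_id = rc$sample_id,
                       replicate_index = rc$replicate_index,
                       status = status, distance_to_barycenter = dist_b,
                       threshold_used = threshold, stringsAsFactors = FALSE)
  retained <- rc[status == "kept" & !(rc$sample_id %in% lonely), ,
                 drop = FALSE]
  list(report = report, retained = retained,
       dropped_samples = sort(unique(c(lonely,
         setdiff(rc$sample_id, report$sample_id[status == "kept"])))))
}

#' Average QC-passed replicates and apply the MOTU filters
#'
#' Read counts are averaged across each sample's kept replicates on the
#' proportion scale (rescaled by the mean replicate depth, so totals stay in
#' read units without depth-weighting the composition; set
#' `average = "counts"` for raw-count averaging). MOTUs with reference
#' similarity < `min_similarity` are then removed, and after RRA conversion
#' MOTUs never reaching `min_max_rra` in any sample are dropped as sporadic;
#' RRA is recomputed after each removal.
#'
#' @param retained Retained plant PCRs from [filter_replicates()].
#' @param catalog A `motu_catalog` table.
#' @param min_similarity Best-match similarity threshold in percent
#'   (default 95; 94.9 is removed).
#' @param min_max_rra Sporadic-occurrence threshold on the maximum RRA of a
#'   MOTU across samples (default 0.025).
#' @param average `"proportion"` (default) or `"counts"`.
#' @return Sample x MOTU averaged read table (data frame with `sample_id`),
#'   filtered; convert with [to_rra()] for the diet profile.
#' @export
motu_filters <- function(retained, catalog, min_similarity = 95,
                         min_max_rra = 0.025,
                         average = c("proportion", "counts")) {
  average <- match.arg(average)
  m <- count_matrix(retained)
  sid <- retained$sample_id
  samples <- unique(sid)
  avg <- t(vapply(samples, function(s) {
    rows <- m[sid == s, , drop = FALSE]
    if (average == "counts") colMeans(rows)
    else colMeans(.row_props(rows)) * mean(rowSums(rows))
  }, numeric(ncol(m))))
  rownames(avg) <- samples

  ## reference-similarity filter
  sim <- catalog$best_similarity[match(colnames(avg), catalog$motu_id)]
  avg <- avg[, !is.na(sim) & sim >= min_similarity, drop = FALSE]

  ## sporadic-occurrence filter on recomputed RRA
  rra <- .row_props(avg)
  avg <- avg[, apply(rra, 2, max) >= min_max_rra, drop = FALSE]

  data.frame(sample_id = samples, as.data.frame(avg, row.names = NULL),
             check.names = FALSE)
}

#' Convert a sample x MOTU read table to relative read abundances
#'
#' Each value becomes its row share: count / total reads in the sample.
#' Zero-total rows are dropped with a warning, so every emitted row sums
#' to 1.
#'
#' @param x Data frame with `sample_id` and numeric MOTU/taxon columns.
#' @return A validated `diet_profile` table.
#' @export
to_rra <- function(x) {
  taxa <- setdiff(names(x), "sample_id")
  m <- as.matrix(x[, taxa, drop = FALSE])
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    warning("dropping ", sum(tot <= 0), " zero-total sample(s): ",
            paste(x$sample_id[tot <= 0], collapse = ", "))
    x <- x[tot > 0, , drop = FALSE]
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  out <- data.frame(sample_id = x$sample_id,
                    as.data.frame(sweep(m, 1, tot, "/"), row.names = NULL),
                    check.names = FALSE)
  validate_table(out, "diet_profile")
}

#' Collapse MOTU columns to a coarser taxonomic rank or category set
#'
#' Sums read counts (or RRA) of MOTUs mapping to the same taxon. `rank` may
#' be a taxonomy rank (`"family"`, `"genus"`, `"species"`, `"finest"`) taken
#' from the catalog, or a named character vector mapping MOTU ids to
#' food-category names.
#'
#' @param x Sample x MOTU data frame (`sample_id` + numeric columns), counts
#'   or RRA.
#' @param catalog A `motu_catalog` table (ignored when `rank` is a map).
#' @param rank Taxonomy rank name or named MOTU -> category map.
#' @param fallback Category for MOTUs the map does not cover; `NULL`
#'   (default) makes unmapped MOTUs an error.
#' @return Data frame of the same kind with taxon columns; totals per row are
#'   conserved.
#' @export
collapse_taxa <- function(x, catalog = NULL, rank = "family",
                          fallback = NULL) {
  motus <- setdiff(names(x), "sample_id")
  if (is.character(rank) && length(rank) == 1 && is.null(names(rank))) {
    if (is.null(catalog)) stop("catalog required for rank-based collapsing")
    tx <- catalog$taxonomy[match(motus, catalog$motu_id)]
    tax <- if (rank == "finest") finest_taxon(tx) else taxon_at_rank(tx, rank)
    ## fall back to the finest resolved rank when the path stops short
    tax[is.na(tax)] <- finest_taxon(tx[is.na(tax)])
  } else {
    tax <- unname(rank[motus])
    if (anyNA(tax)) {
      if (is.null(fallback))
        stop("no category mapping for MOTU(s): ",
             paste(motus[is.na(tax)], collapse = ", "))
      tax[is.na(tax)] <- fallback
    }
  }
  m <- as.matrix(x[, motus, drop = FALSE])
  collapsed <- t(rowsum(t(m), group = tax))
  data.frame(sample_id = x$sample_id,
             as.data.frame(collapsed, row.names = NULL), check.names = FALSE)
}

#' Plant-marker pipeline: QC, filters, and the MOTU-level diet profile
#'
#' Chains [replicate_distances()], [qc_threshold()], [filter_replicates()],
#' [motu_filters()] and [to_rra()].
#'
#' @param read_counts A `read_counts` table (plant sample rows and control
#'   rows are taken from it).
#' @param catalog A `motu_catalog` table.
#' @param threshold Optional explicit distance threshold; estimated from the
#'   data via [qc_threshold()] when `NULL`.
#' @param min_reads,k,method,min_similarity,min_max_rra,average See the
#'   stage functions.
#' @param min_n Minimum sample distances for threshold estimation.
#' @return List: `profile` (MOTU-level `diet_profile`), `counts` (averaged
#'   filtered read table), `qc_report`, `threshold`, `dropped_samples`.
#' @export
build_diet_profile <- function(read_counts, catalog, threshold = NULL,
                               min_reads = 1000, k = 5,
                               method = c("bray", "hellinger"),
                               min_similarity = 95, min_max_rra = 0.025,
                               average = c("proportion", "counts"),
                               min_n = 20) {
  method <- match.arg(method); average <- match.arg(average)
  plant <- read_counts[read_counts$marker == "plant" &
                         read_counts$control_kind == "none", , drop = FALSE]
  controls <- read_counts[read_counts$control_kind != "none", , drop = FALSE]
  if (is.null(threshold)) {
    rd <- replicate_distances(plant, method)
    threshold <- qc_threshold(rd$sample_distances, min_n = min_n)
  }
  qc <- filter_replicates(plant, controls, threshold, min_reads, k, method)
  counts <- motu_filters(qc$retained, catalog, min_similarity, min_max_rra,
                         average)
  list(profile = to_rra(counts), counts = counts, qc_report = qc$report,
       threshold = threshold, dropped_samples = qc$dropped_samples)
}
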