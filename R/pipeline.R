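## End-to-end runner: simulate/read inputs -> host ID -> plant QC and diet
## profiles -> niche metrics -> ordination -> overlap drivers, with a plain
## TSV output directory and a run manifest.

#' Default pipeline configuration
#'
#' Thresholds mirror the filtering rules of the protocol: mammal marker
#' (1% within-PCR share, 40 bp, 500 reads, 2x dominance), plant marker
#' (1000 reads, 5th-percentile replicate-distance threshold, k = 5 control
#' neighbourhood, 95% reference similarity, 2.5% maximum RRA), cervid index
#' (12/16 plots, 25 groups / 100 m2), beta regression (8 transects
#' minimum), ordination (permutation count and seed).
#'
#' @param out_dir Output directory for result TSVs and the manifest.
#' @param seed Master seed (simulation and permutation streams).
#' @param n_perm Permutations for ordination tests.
#' @return Named list of configuration values.
#' @export
default_config <- function(out_dir = tempfile("cervid_run_"), seed = 1L,
                           n_perm = 999) {
  list(
    simulate = TRUE, inputs = NULL, out_dir = out_dir, seed = seed,
    mammal_min_share = 0.01, mammal_min_length_bp = 40,
    mammal_min_reads = 500, dominance = 2,
    plant_min_reads = 1000, qc_quantile = 0.05, knn_k = 5,
    distance_method = "bray",
    min_similarity = 95, min_max_rra = 0.025,
    collapse_rank = "family",
    n_perm = n_perm, ordination_seasons = c("spring", "winter",
                                            "summer_autumn"),
    drivers_min_n = 8, inter_mode = "mean_diet",
    run_selectivity = TRUE)
}

.config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v), collapse = ","), character(1)), sep = "=",
    collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            0xFFFFFFFF)
}

#' Run the complete diet-analysis pipeline
#'
#' Chains every stage on simulated or user-supplied inputs and writes one
#' TSV per result table plus a manifest recording the configuration hash,
#' seed and per-stage attrition counts (samples in, host-assigned,
#' QC-passed, profiled).
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file of the same keys. When `simulate` is `FALSE`, `inputs`
#'   must name the `read_counts`, `motu_catalog`, `sample_metadata` files
#'   (and optionally `availability`, `pellet_counts`, `covariates`).
#' @return Invisibly, a list with all in-memory results (`data`,
#'   `host`, `profile`, `category_profile`, `richness`, `dunn`, `dnw`,
#'   `overlap`, `overlap_summary`, `selectivity`, `ordinations`, `drivers`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config) && length(config) == 1)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  config <- utils::modifyList(default_config(), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[pipeline] ", ...)
  log_msg("thresholds: mammal ", config$mammal_min_share * 100, "% share / ",
          config$mammal_min_length_bp, " bp / ", config$mammal_min_reads,
          " reads; plant ", config$plant_min_reads, " reads / q",
          config$qc_quantile, " distance / ", config$min_similarity,
          "% similarity / ", config$min_max_rra * 100, "% max RRA")

  ## stage 1: inputs
  if (isTRUE(config$simulate)) {
    data <- simulate_dataset(make_default_spec(), seed = config$seed)
  } else {
    if (is.null(config$inputs))
      stop("stage input: config$inputs required when simulate = FALSE")
    req <- c("read_counts", "motu_catalog", "sample_metadata")
    miss <- setdiff(req, names(config$inputs))
    if (length(miss)) stop("stage input: missing input path(s): ",
                           paste(miss, collapse = ", "))
    data <- list(
      read_counts = read_table(config$inputs$read_counts, "read_counts"),
      motu_catalog = read_table(config$inputs$motu_catalog, "motu_catalog"),
      sample_metadata = read_table(config$inputs$sample_metadata,
                                   "sample_metadata"))
    for (opt in c("availability", "pellet_counts", "covariates"))
      if (!is.null(config$inputs[[opt]]))
        data[[opt]] <- read_table(config$inputs[[opt]], opt)
  }
  n_in <- length(unique(data$sample_metadata$sample_id))
  log_msg("samples in: ", n_in)

  ## stage 2: host species
  host <- host_assignments(data$read_counts, data$motu_catalog,
                           config$mammal_min_share,
                           config$mammal_min_length_bp,
                           config$mammal_min_reads, config$dominance)
  assigned <- host[host$status == "assigned", , drop = FALSE]
  log_msg("host-assigned: ", nrow(assigned), " (",
          nrow(host) - nrow(assigned), " discarded)")

  ## stage 3: plant QC + profiles
  dq <- build_diet_profile(
    data$read_counts, data$motu_catalog,
    min_reads = config$plant_min_reads, k = config$knn_k,
    method = config$distance_method, min_similarity = config$min_similarity,
    min_max_rra = config$min_max_rra)
  profile <- dq$profile
  ## restrict to samples with a host assignment
  profile <- profile[profile$sample_id %in% assigned$sample_id, ,
                     drop = FALSE]
  species <- assigned$assigned_species[match(profile$sample_id,
                                             assigned$sample_id)]
  log_msg("QC-passed and profiled: ", nrow(profile))

  ## stage 4: metrics
  rich <- richness(profile, data$sample_metadata, species)
  dunn <- suppressWarnings(dunn_bh(rich$S, rich$species))
  dnwt <- dnw_table(profile, data$sample_metadata, species)
  ov <- overlap_table(profile, data$sample_metadata, species,
                      inter_mode = config$inter_mode)
  ovs <- overlap_summary(ov)

  ## stage 5: selectivity (needs availability + category map)
  sel <- NULL
  if (isTRUE(config$run_selectivity)) {
    if (is.null(data$availability))
      stop("stage selectivity: availability table required ",
           "(set run_selectivity = FALSE to skip)")
    cat_profile <- if (!is.null(data$category_map))
      to_rra(collapse_taxa(profile, rank = data$category_map,
                           fallback = "other"))
    else to_rra(collapse_taxa(profile, data$motu_catalog,
                              rank = config$collapse_rank))
    sel <- selectivity_table(cat_profile, data$availability,
                             data$sample_metadata, species)
  } else cat_profile <- NULL

  ## stage 6: ordination per landscape x season
  meta_i <- match(profile$sample_id, data$sample_metadata$sample_id)
  strata <- unique(data.frame(
    landscape = data$sample_metadata$landscape[meta_i],
    season = data$sample_metadata$season[meta_i]))
  ords <- list()
  for (r in seq_len(nrow(strata))) {
    if (!(strata$season[r] %in% config$ordination_seasons)) next
    in_str <- data$sample_metadata$landscape[meta_i] == strata$landscape[r] &
      data$sample_metadata$season[meta_i] == strata$season[r]
    lb <- species[in_str]
    if (sum(table(lb) >= 2) < 2) next
    key <- paste(strata$landscape[r], strata$season[r], sep = ".")
    ords[[key]] <- tryCatch(
      ordinate_stratum(profile[in_str, , drop = FALSE], lb,
                       n_perm = config$n_perm,
                       seed = child_seed(config$seed, key)),
      error = function(e) NULL)
  }

  ## stage 7: drivers
  drv <- NULL
  if (!is.null(data$covariates))
    drv <- drivers_analysis(ov, data$covariates,
                            min_n = config$drivers_min_n)

  ## outputs
  manifest <- c(
    paste0("config_hash: ", .config_hash(config)),
    paste0("seed: ", config$seed),
    paste0("r_version: ", R.version.string),
    paste0("samples_in: ", n_in),
    paste0("host_assigned: ", nrow(assigned)),
    paste0("qc_passed_samples: ", nrow(profile)),
    paste0("profiled_taxa: ", ncol(profile) - 1L),
    paste0("qc_threshold: ", format(dq$threshold, digits = 6)))
  out <- config$out_dir
  write_table(profile, file.path(out, "diet_profile.tsv"), "diet_profile")
  utils::write.table(host, file.path(out, "host_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dq$qc_report, file.path(out, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rich, file.path(out, "richness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dunn, file.path(out, "dunn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dnwt, file.path(out, "dnw.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_table(ov, file.path(out, "overlap.tsv"), "overlap")
  utils::write.table(ovs, file.path(out, "overlap_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sel)) {
    utils::write.table(sel$records, file.path(out, "selectivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sel$summary, file.path(out, "selectivity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(drv) && !is.null(drv$fits))
    utils::write.table(drv$fits, file.path(out, "driver_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(manifest, file.path(out, "manifest.txt"))
  log_msg("done; outputs in ", out)

  invisible(list(data = data, host = host, profile = profile,
                 category_profile = cat_profile, qc = dq, richness = rich,
                 dunn = dunn, dnw = dnwt, overlap = ov,
                 overlap_summary = ovs, selectivity = sel,
                 ordinations = ords, drivers = drv, manifest = manifest))
}
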