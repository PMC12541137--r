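# Fixture builders shared across the suite. Everything is constructed in
# code; no data files.

# minimal mammal catalog: four exact-match cervid MOTUs, one short artifact,
# one non-reference MOTU
tiny_mammal_catalog <- function() {
  validate_table(data.frame(
    motu_id = c("Mmo", "Mro", "Mre", "Mfa", "Mart", "Mnoref"),
    marker = "mammal",
    length_bp = c(72L, 68L, 70L, 74L, 39L, 66L),
    best_similarity = c(100, 100, 100, 100, 60, 88),
    taxonomy = c("Cervidae;Alces;Alces alces",
                 "Cervidae;Capreolus;Capreolus capreolus",
                 "Cervidae;Cervus;Cervus elaphus",
                 "Cervidae;Dama;Dama dama",
                 "unassigned", "Suidae;Sus;Sus scrofa"),
    is_reference_exact = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE), "motu_catalog")
}

# plant catalog with controllable similarities
tiny_plant_catalog <- function(similarities = c(A = 100, B = 100, C = 100)) {
  n <- length(similarities)
  validate_table(data.frame(
    motu_id = names(similarities), marker = "plant",
    length_bp = 48L, best_similarity = unname(similarities),
    taxonomy = paste0("Fam", seq_len(n), ";Gen", seq_len(n)),
    is_reference_exact = unname(similarities) == 100,
    stringsAsFactors = FALSE), "motu_catalog")
}

# build a plant read_counts table from a named list
#   list(S1 = rbind(rep1_counts, rep2_counts, ...), ...)
# counts are named vectors over the same MOTU set
plant_counts_table <- function(samples, controls = NULL) {
  rows <- list()
  for (s in names(samples)) {
    m <- samples[[s]]
    for (r in seq_len(nrow(m)))
      rows[[length(rows) + 1L]] <- data.frame(
        pcr_id = sprintf("%s-P%d", s, r), sample_id = s, marker = "plant",
        replicate_index = r, control_kind = "none",
        as.data.frame(t(m[r, ]), check.names = FALSE),
        stringsAsFactors = FALSE)
  }
  if (!is.null(controls)) for (r in seq_len(nrow(controls)))
    rows[[length(rows) + 1L]] <- data.frame(
      pcr_id = sprintf("CTRL-%d", r), sample_id = NA_character_,
      marker = "plant", replicate_index = r, control_kind = "pcr_negative",
      as.data.frame(t(controls[r, ]), check.names = FALSE),
      stringsAsFactors = FALSE)
  validate_table(do.call(rbind, rows), "read_counts")
}

# a diet profile from a row-named RRA matrix
profile_from_matrix <- function(m) {
  validate_table(
    data.frame(sample_id = rownames(m), as.data.frame(m, row.names = NULL),
               check.names = FALSE), "diet_profile")
}

# metadata rows consistent with the season/date mapping
tiny_metadata <- function(sample_id, transect_id = "T01",
                          landscape = "coastal_boreal", season = "winter",
                          putative_species = "moose") {
  dates <- c(winter = "2017-01-15", spring = "2016-04-20",
             summer_autumn = "2016-07-10")
  validate_table(data.frame(
    sample_id = sample_id, transect_id = transect_id, landscape = landscape,
    season = season, collection_date = unname(dates[season]),
    putative_species = putative_species, stringsAsFactors = FALSE),
    "sample_metadata")
}

# scaled-down community spec for simulation-heavy tests
small_spec <- function(...) {
  spec <- make_default_spec()
  spec$n_diet_transects <- c(coastal_boreal = 4, boreo_nemoral = 4)
  spec$n_pellet_transects <- c(coastal_boreal = 12, boreo_nemoral = 12)
  mods <- list(...)
  for (nm in names(mods)) spec[[nm]] <- mods[[nm]]
  spec
}

# brute-force beta log-likelihood (independent oracle for betareg_fit)
beta_loglik_oracle <- function(beta0, beta1 = NULL, logphi, y, x = NULL) {
  eta <- beta0 + if (is.null(beta1)) 0 else beta1 * x
  mu <- plogis(eta)
  phi <- exp(logphi)
  sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}
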