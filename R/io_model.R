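#' @keywords internal
"_PACKAGE"

## Canonical enum levels used across all tables -------------------------------

cd_enums <- list(
  marker          = c("mammal", "plant"),
  control_kind    = c("none", "extraction_blank", "pcr_negative",
                      "pcr_positive", "primer_blank"),
  landscape       = c("coastal_boreal", "boreo_nemoral"),
  season          = c("spring", "summer_autumn", "winter"),
  putative_species = c("moose", "roe", "red", "fallow", "unknown"),
  species         = c("moose", "roe", "red", "fallow"),
  height_range    = c("0-1.5m", "0-1.8m", "0-2.3m", "0-3m"),
  species_class   = c("large", "small"),
  overlap_kind    = c("intra", "inter")
)

## Fixed (non-matrix) columns per schema. For `read_counts` and `diet_profile`
## every column beyond these is a MOTU / taxon column.
cd_schema_defs <- list(
  read_counts = list(
    fixed = c("pcr_id", "sample_id", "marker", "replicate_index", "control_kind"),
    matrix_cols = TRUE),
  motu_catalog = list(
    fixed = c("motu_id", "marker", "length_bp", "best_similarity",
              "taxonomy", "is_reference_exact"),
    matrix_cols = FALSE),
  sample_metadata = list(
    fixed = c("sample_id", "transect_id", "landscape", "season",
              "collection_date", "putative_species"),
    matrix_cols = FALSE),
  diet_profile = list(
    fixed = c("sample_id"),
    matrix_cols = TRUE),
  availability = list(
    fixed = c("transect_id", "season", "height_range", "category", "proportion"),
    matrix_cols = FALSE),
  pellet_counts = list(
    fixed = c("transect_id", "year", "plot_id", "plot_area_m2",
              "species_class", "pellet_groups", "surveyed"),
    matrix_cols = FALSE),
  covariates = list(
    fixed = c("transect_id", "cervid_index", "habitat_shannon", "arable_prop"),
    matrix_cols = FALSE),
  overlap = list(
    fixed = c("transect_id", "season", "landscape", "kind", "species_a",
              "species_b", "pianka", "n_samples_a", "n_samples_b"),
    matrix_cols = FALSE)
)

#' Names of the table schemas understood by [read_table()]
#' @return Character vector of schema names.
#' @export
cd_schemas <- function() names(cd_schema_defs)

## ---------------------------------------------------------------------------

#' Read a typed pipeline table from TSV or CSV
#'
#' Reads one of the pipeline's tabular inputs/outputs, coerces column types,
#' converts percent-scaled proportion columns to \[0,1\], and validates all
#' schema invariants (enum membership, row-sum constraints, key uniqueness,
#' season/date consistency). The delimiter is sniffed from the header line
#' (tab canonical, comma accepted).
#'
#' @param path Path to a TSV/CSV file whose header matches the schema
#'   (column order free).
#' @param schema One of [cd_schemas()].
#' @return A validated `data.frame` carrying a `"cd_schema"` attribute.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, cd_schemas())
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "", na.strings = c("NA", ""))
  validate_table(x, schema)
}

#' Validate a data frame against a pipeline schema
#'
#' @param x A data frame.
#' @param schema One of [cd_schemas()].
#' @return `x`, coerced and validated, with the `"cd_schema"` attribute set.
#' @export
validate_table <- function(x, schema) {
  schema <- match.arg(schema, cd_schemas())
  def <- cd_schema_defs[[schema]]
  missing_cols <- setdiff(def$fixed, names(x))
  if (length(missing_cols))
    stop("schema error [", schema, "]: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ## fixed columns first, matrix columns keep their order
  x <- x[, c(def$fixed, setdiff(names(x), def$fixed)), drop = FALSE]
  if (nrow(x) == 0L) {
    ## header-only table: nothing to validate beyond column presence
    attr(x, "cd_schema") <- schema
    return(x)
  }
  x <- switch(schema,
    read_counts     = .validate_read_counts(x),
    motu_catalog    = .validate_motu_catalog(x),
    sample_metadata = .validate_sample_metadata(x),
    diet_profile    = .validate_diet_profile(x),
    availability    = .validate_availability(x),
    pellet_counts   = .validate_pellet_counts(x),
    covariates      = .validate_covariates(x),
    overlap         = .validate_overlap(x))
  attr(x, "cd_schema") <- schema
  x
}

#' Write a pipeline table as TSV
#'
#' Columns are emitted in stable schema order (fixed columns first). The
#' written file round-trips through [read_table()] exactly for integer and
#' string fields and to ~1e-15 relative precision for proportions.
#'
#' @param x A validated table (see [validate_table()]).
#' @param path Output file path.
#' @param schema Schema name; defaults to the table's `"cd_schema"` attribute.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema = attr(x, "cd_schema")) {
  if (is.null(schema))
    stop("table has no cd_schema attribute; pass `schema` explicitly")
  x <- validate_table(as.data.frame(x), schema)
  ok <- try(utils::write.table(x, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("I/O error writing ", path, ": ", attr(ok, "condition")$message)
  invisible(path)
}

## -- per-schema validators ---------------------------------------------------

.check_enum <- function(x, col, levels, schema) {
  v <- as.character(x[[col]])
  bad <- which(!(is.na(v) & col == "sample_id") & !v %in% levels & !is.na(v))
  if (length(bad))
    stop("validation error [", schema, "]: column '", col, "' row ", bad[1],
         " has value '", v[bad[1]], "'; allowed: ",
         paste(levels, collapse = ", "))
  v
}

.check_nonneg_int <- function(x, col, schema, strict_pos = FALSE) {
  v <- x[[col]]
  if (!is.numeric(v)) stop("validation error [", schema, "]: '", col,
                           "' must be numeric")
  if (any(!is.finite(v)) || any(v < as.numeric(strict_pos)) ||
      any(v != round(v)))
    stop("validation error [", schema, "]: '", col, "' must be ",
         if (strict_pos) "positive" else "non-negative", " integers (row ",
         which(!is.finite(v) | v < as.numeric(strict_pos) | v != round(v))[1],
         ")")
  as.integer(round(v))
}

.as_prop <- function(v, col, schema) {
  if (!is.numeric(v)) stop("validation error [", schema, "]: '", col,
                           "' must be numeric")
  if (any(v > 1, na.rm = TRUE)) v <- v / 100  # percent column convention
  if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    stop("validation error [", schema, "]: '", col, "' outside [0,1] at row ",
         which(v < -1e-12 | v > 1 + 1e-12)[1])
  pmin(pmax(v, 0), 1)
}

.matrix_cols <- function(x, schema) {
  setdiff(names(x), cd_schema_defs[[schema]]$fixed)
}

.validate_read_counts <- function(x) {
  motus <- .matrix_cols(x, "read_counts")
  if (length(motus) < 1)
    stop("validation error [read_counts]: at least one MOTU column required")
  x$pcr_id <- as.character(x$pcr_id)
  x$sample_id <- as.character(x$sample_id)
  x$marker <- .check_enum(x, "marker", cd_enums$marker, "read_counts")
  x$replicate_index <- .check_nonneg_int(x, "replicate_index", "read_counts",
                                         strict_pos = TRUE)
  x$control_kind <- .check_enum(x, "control_kind", cd_enums$control_kind,
                                "read_counts")
  for (m in motus) x[[m]] <- .check_nonneg_int(x, m, "read_counts")
  is_ctrl <- x$control_kind != "none"
  if (any(is.na(x$sample_id) & !is_ctrl))
    stop("validation error [read_counts]: empty sample_id on non-control row ",
         which(is.na(x$sample_id) & !is_ctrl)[1])
  key <- paste(x$sample_id, x$marker, x$replicate_index)[!is_ctrl]
  if (anyDuplicated(key))
    stop("validation error [read_counts]: duplicate (sample_id, marker, ",
         "replicate_index) key: ", key[duplicated(key)][1])
  x
}

.validate_motu_catalog <- function(x) {
  x$motu_id <- as.character(x$motu_id)
  if (anyDuplicated(x$motu_id))
    stop("validation error [motu_catalog]: duplicate motu_id ",
         x$motu_id[duplicated(x$motu_id)][1])
  x$marker <- .check_enum(x, "marker", cd_enums$marker, "motu_catalog")
  x$length_bp <- .check_nonneg_int(x, "length_bp", "motu_catalog",
                                   strict_pos = TRUE)
  if (!is.numeric(x$best_similarity) ||
      any(x$best_similarity < 0 | x$best_similarity > 100))
    stop("validation error [motu_catalog]: best_similarity must lie in [0,100]")
  x$taxonomy <- as.character(x$taxonomy)
  if (any(is.na(x$taxonomy) | x$taxonomy == ""))
    stop("validation error [motu_catalog]: empty taxonomy at row ",
         which(is.na(x$taxonomy) | x$taxonomy == "")[1],
         " (use 'unassigned' if unknown)")
  x$is_reference_exact <- as.logical(x$is_reference_exact)
  if (any(is.na(x$is_reference_exact)))
    stop("validation error [motu_catalog]: is_reference_exact must be TRUE/FALSE")
  x
}

.season_of_month <- function(m) {
  ifelse(m %in% c(11, 12, 1, 2, 3), "winter",
         ifelse(m %in% c(4, 5), "spring", "summer_autumn"))
}

.validate_sample_metadata <- function(x) {
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id))
    stop("validation error [sample_metadata]: duplicate sample_id ",
         x$sample_id[duplicated(x$sample_id)][1])
  x$transect_id <- as.character(x$transect_id)
  x$landscape <- .check_enum(x, "landscape", cd_enums$landscape,
                             "sample_metadata")
  x$season <- .check_enum(x, "season", cd_enums$season, "sample_metadata")
  x$collection_date <- as.character(x$collection_date)
  mth <- as.integer(format(as.Date(x$collection_date), "%m"))
  if (any(is.na(mth)))
    stop("validation error [sample_metadata]: unparseable collection_date ",
         "at row ", which(is.na(mth))[1])
  bad <- which(.season_of_month(mth) != x$season)
  if (length(bad))
    stop("validation error [sample_metadata]: season '", x$season[bad[1]],
         "' inconsistent with collection_date ", x$collection_date[bad[1]],
         " at row ", bad[1],
         " (winter = Nov-Mar, spring = Apr-May, summer_autumn = Jun-Oct)")
  x$putative_species <- .check_enum(x, "putative_species",
                                    cd_enums$putative_species,
                                    "sample_metadata")
  x
}

.validate_diet_profile <- function(x) {
  taxa <- .matrix_cols(x, "diet_profile")
  if (length(taxa) < 1)
    stop("validation error [diet_profile]: at least one taxon column required")
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id))
    stop("validation error [diet_profile]: duplicate sample_id ",
         x$sample_id[duplicated(x$sample_id)][1])
  for (tc in taxa) {
    if (!is.numeric(x[[tc]]))
      stop("validation error [diet_profile]: non-numeric taxon column '",
           tc, "'")
    if (any(x[[tc]] < -1e-12 | x[[tc]] > 1 + 1e-12))
      stop("validation error [diet_profile]: RRA outside [0,1] in '", tc, "'")
  }
  if (nrow(x)) {
    rs <- rowSums(x[, taxa, drop = FALSE])
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad))
      stop("validation error [diet_profile]: row ", bad[1], " (sample ",
           x$sample_id[bad[1]], ") sums to ", format(rs[bad[1]]),
           ", expected 1")
  }
  x
}

.validate_availability <- function(x) {
  x$transect_id <- as.character(x$transect_id)
  x$season <- .check_enum(x, "season", cd_enums$season, "availability")
  x$height_range <- .check_enum(x, "height_range", cd_enums$height_range,
                                "availability")
  x$category <- as.character(x$category)
  x$proportion <- .as_prop(x$proportion, "proportion", "availability")
  if (nrow(x)) {
    grp <- paste(x$transect_id, x$season, x$height_range)
    sums <- tapply(x$proportion, grp, sum)
    bad <- which(abs(sums - 1) > 1e-9)
    if (length(bad))
      stop("validation error [availability]: proportions in group (",
           names(sums)[bad[1]], ") sum to ", format(sums[bad[1]]),
           ", expected 1")
  }
  x
}

.validate_pellet_counts <- function(x) {
  x$transect_id <- as.character(x$transect_id)
  x$year <- .check_nonneg_int(x, "year", "pellet_counts")
  x$plot_id <- .check_nonneg_int(x, "plot_id", "pellet_counts",
                                 strict_pos = TRUE)
  if (any(x$plot_id > 16))
    stop("validation error [pellet_counts]: plot_id must be 1-16")
  if (!all(x$plot_area_m2 %in% c(10, 100)))
    stop("validation error [pellet_counts]: plot_area_m2 must be 10 or 100")
  x$species_class <- .check_enum(x, "species_class", cd_enums$species_class,
                                 "pellet_counts")
  x$pellet_groups <- .check_nonneg_int(x, "pellet_groups", "pellet_counts")
  x$surveyed <- as.logical(x$surveyed)
  if (any(is.na(x$surveyed)))
    stop("validation error [pellet_counts]: surveyed must be TRUE/FALSE")
  x
}

.validate_covariates <- function(x) {
  x$transect_id <- as.character(x$transect_id)
  if (anyDuplicated(x$transect_id))
    stop("validation error [covariates]: duplicate transect_id ",
         x$transect_id[duplicated(x$transect_id)][1])
  if (!is.numeric(x$cervid_index) || any(x$cervid_index < 0))
    stop("validation error [covariates]: cervid_index must be >= 0")
  if (!is.numeric(x$habitat_shannon) || any(x$habitat_shannon < 0))
    stop("validation error [covariates]: habitat_shannon must be >= 0")
  x$arable_prop <- .as_prop(x$arable_prop, "arable_prop", "covariates")
  x
}

.validate_overlap <- function(x) {
  x$transect_id <- as.character(x$transect_id)
  x$season <- .check_enum(x, "season", cd_enums$season, "overlap")
  x$landscape <- .check_enum(x, "landscape", cd_enums$landscape, "overlap")
  x$kind <- .check_enum(x, "kind", cd_enums$overlap_kind, "overlap")
  x$species_a <- .check_enum(x, "species_a", cd_enums$species, "overlap")
  x$species_b <- .check_enum(x, "species_b", cd_enums$species, "overlap")
  if (any(x$kind == "intra" & x$species_a != x$species_b))
    stop("validation error [overlap]: intra rows must have species_a == species_b")
  if (!is.numeric(x$pianka) ||
      any(x$pianka < -1e-12 | x$pianka > 1 + 1e-12, na.rm = TRUE))
    stop("validation error [overlap]: pianka outside [0,1]")
  x$n_samples_a <- .check_nonneg_int(x, "n_samples_a", "overlap")
  x$n_samples_b <- .check_nonneg_int(x, "n_samples_b", "overlap")
  x
}

## -- small shared helpers ----------------------------------------------------

#' Extract the read-count matrix from a read-count table
#' @param rc A `read_counts` table.
#' @return Numeric matrix (rows = PCRs, named by `pcr_id`; cols = MOTUs).
#' @export
count_matrix <- function(rc) {
  motus <- setdiff(names(rc), cd_schema_defs$read_counts$fixed)
  m <- as.matrix(rc[, motus, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rc$pcr_id
  m
}

#' Extract the RRA matrix from a diet profile
#' @param profile A `diet_profile` table.
#' @return Numeric matrix (rows named by `sample_id`).
#' @export
profile_matrix <- function(profile) {
  taxa <- setdiff(names(profile), "sample_id")
  m <- as.matrix(profile[, taxa, drop = FALSE])
  rownames(m) <- profile$sample_id
  m
}

.as_profile <- function(m) {
  out <- data.frame(sample_id = rownames(m), as.data.frame(m),
                    check.names = FALSE, row.names = NULL)
  validate_table(out, "diet_profile")
}

#' Taxon name at a taxonomy rank
#'
#' Taxonomy paths are semicolon-delimited `family;genus;species` strings with
#' trailing ranks omitted when unresolved.
#'
#' @param taxonomy Character vector of taxonomy paths.
#' @param rank `"family"`, `"genus"` or `"species"`.
#' @return Character vector; `NA` where the path does not reach the rank.
#' @export
taxon_at_rank <- function(taxonomy, rank = c("family", "genus", "species")) {
  rank <- match.arg(rank)
  idx <- match(rank, c("family", "genus", "species"))
  vapply(strsplit(as.character(taxonomy), ";", fixed = TRUE),
         function(p) if (length(p) >= idx && nzchar(p[idx])) p[idx]
                     else NA_character_,
         character(1))
}

#' Finest resolved taxon of a taxonomy path
#' @param taxonomy Character vector of taxonomy paths.
#' @return Last non-empty element of each path.
#' @export
finest_taxon <- function(taxonomy) {
  vapply(strsplit(as.character(taxonomy), ";", fixed = TRUE),
         function(p) { p <- p[nzchar(p)]; p[length(p)] }, character(1))
}
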