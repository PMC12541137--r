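## Host (deer) species assignment from mammal-marker read counts.

#' Filter a mammal-marker PCR
#'
#' Removes MOTUs contributing < 1% of the PCR's reads (mostly artifacts) and
#' MOTUs shorter than 40 bp (bacterial fragments), then rejects the PCR if
#' the remaining total is below 500 reads (poor amplification).
#'
#' @param counts Named non-negative integer vector (MOTU id -> reads) for one
#'   mammal-marker PCR.
#' @param catalog A `motu_catalog` table.
#' @param min_share Within-PCR read-share threshold (default 0.01).
#' @param min_length_bp Minimum amplicon length (default 40).
#' @param min_reads Minimum retained total (default 500; exactly 500 is kept).
#' @return List with `counts` (retained named vector) and `rejected`
#'   (logical; TRUE when the filtered total is < `min_reads`).
#' @export
filter_mammal_pcr <- function(counts, catalog, min_share = 0.01,
                              min_length_bp = 40, min_reads = 500) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total > 0) {
    keep <- counts / total >= min_share
    len <- catalog$length_bp[match(names(counts), catalog$motu_id)]
    keep <- keep & !is.na(len) & len >= min_length_bp
    counts <- counts[keep]
  }
  list(counts = counts, rejected = sum(counts) < min_reads)
}

#' Assign a host species from a filtered mammal PCR
#'
#' The candidate is the most abundant MOTU that exactly matches a reference
#' sequence. When more than one mammal species is detected among the retained
#' exact-match MOTUs, the dominant species' top MOTU must be at least
#' `dominance` (2x) as abundant as the runner-up species' top MOTU; otherwise
#' the sample is discarded as ambiguous. With a single MOTU the dominance
#' ratio is `Inf`. Ties for the most abundant MOTU are ambiguous.
#'
#' @param counts Named read-count vector that passed [filter_mammal_pcr()].
#' @param catalog A `motu_catalog` table.
#' @param dominance Required abundance ratio (default 2).
#' @return A one-row data frame: `status` (one of `assigned`,
#'   `discarded_low_reads`, `discarded_ambiguous`,
#'   `discarded_no_reference_match`), `assigned_species` (species-level taxon
#'   of the dominant MOTU, `NA` unless assigned), `dominant_motu`,
#'   `dominance_ratio`.
#' @export
assign_species <- function(counts, catalog, dominance = 2) {
  res <- function(status, sp = NA_character_, motu = NA_character_,
                  ratio = NA_real_)
    data.frame(status = status, assigned_species = sp, dominant_motu = motu,
               dominance_ratio = ratio, stringsAsFactors = FALSE)
  counts <- sort(counts[counts > 0], decreasing = TRUE)
  if (!length(counts)) return(res("discarded_low_reads"))
  idx <- match(names(counts), catalog$motu_id)
  exact <- catalog$is_reference_exact[idx]
  spp <- taxon_at_rank(catalog$taxonomy[idx], "species")
  if (!any(exact, na.rm = TRUE)) return(res("discarded_no_reference_match"))
  keep <- which(exact & !is.na(spp))
  if (!length(keep)) return(res("discarded_no_reference_match"))
  counts <- counts[keep]; spp <- spp[keep]
  ## top MOTU per detected species
  top <- tapply(counts, spp, max)
  top <- sort(top, decreasing = TRUE)
  if (length(top) == 1) {
    ratio <- if (length(counts) == 1) Inf else Inf
    lead <- names(counts)[which.max(counts)]
    return(res("assigned", names(top)[1], lead, ratio))
  }
  if (top[1] == top[2]) return(res("discarded_ambiguous", ratio = 1))
  ratio <- as.numeric(top[1] / top[2])
  lead_sp <- names(top)[1]
  lead <- names(counts)[spp == lead_sp][which.max(counts[spp == lead_sp])]
  if (ratio < dominance)
    return(res("discarded_ambiguous", motu = lead, ratio = ratio))
  res("assigned", lead_sp, lead, ratio)
}

#' Host-species assignment for every mammal-marker PCR of a dataset
#'
#' Applies [filter_mammal_pcr()] and [assign_species()] per sample and maps
#' the Latin species-level assignment back to the deer species codes.
#'
#' @param read_counts A `read_counts` table (both markers accepted; only
#'   mammal-marker, non-control rows are used).
#' @param catalog A `motu_catalog` table.
#' @inheritParams filter_mammal_pcr
#' @inheritParams assign_species
#' @return Data frame with one row per mammal PCR: `sample_id`, `status`,
#'   `assigned_species` (deer code where the Latin name is a known cervid,
#'   otherwise the species-level taxon), `dominant_motu`, `dominance_ratio`.
#' @export
host_assignments <- function(read_counts, catalog, min_share = 0.01,
                             min_length_bp = 40, min_reads = 500,
                             dominance = 2) {
  rc <- read_counts[read_counts$marker == "mammal" &
                      read_counts$control_kind == "none", , drop = FALSE]
  if (!nrow(rc)) stop("no mammal-marker sample PCRs in read_counts")
  m <- count_matrix(rc)
  latin <- cervid_latin()
  out <- lapply(seq_len(nrow(m)), function(i) {
    f <- filter_mammal_pcr(m[i, ], catalog, min_share, min_length_bp,
                           min_reads)
    if (f$rejected)
      return(data.frame(status = "discarded_low_reads",
                        assigned_species = NA_character_,
                        dominant_motu = NA_character_,
                        dominance_ratio = NA_real_, stringsAsFactors = FALSE))
    assign_species(f$counts, catalog, dominance)
  })
  out <- do.call(rbind, out)
  code <- names(latin)[match(out$assigned_species, latin)]
  out$assigned_species <- ifelse(is.na(code), out$assigned_species, code)
  cbind(data.frame(sample_id = rc$sample_id, stringsAsFactors = FALSE), out)
}
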