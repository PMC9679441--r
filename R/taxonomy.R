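# Percent-identity computation and threshold-based taxonomic assignment
# from tabular best-hit files (BLAST-style: identical sites / query size).

#' Percent identity from identical sites and query size
#'
#' `100 * identical_sites / query_size`, rounded half-away-from-zero to one
#' decimal (the rounding that reproduces printed similarity scores such as
#' 296/311 -> 95.2).
#'
#' @param identical_sites Integer vector, `0 <= identical_sites <= query_size`.
#' @param query_size Positive integer vector (aligned length).
#' @return Numeric vector of percent identities with one decimal.
#' @export
#' @examples
#' percent_identity(313, 313)  # 100.0
#' percent_identity(312, 313)  # 99.7
#' percent_identity(217, 302)  # 71.9
percent_identity <- function(identical_sites, query_size) {
  if (any(query_size <= 0)) stop("query_size must be positive")
  if (any(identical_sites < 0 | identical_sites > query_size)) {
    stop("identical_sites must lie in [0, query_size]")
  }
  v <- 100 * identical_sites / query_size
  floor(v * 10 + 0.5) / 10
}

#' Assignment thresholds for rank-level taxonomy
#'
#' @param species_min Minimum percent identity for a species-level
#'   assignment; the comparison is strict (`identity > species_min`), so
#'   exactly 95.0 is *not* assigned to species under the default 95.
#' @param coarser Optional data.frame with columns `rank` and `min_percent`
#'   giving strictly decreasing thresholds for coarser ranks (e.g. genus,
#'   family, order). No defaults are supplied; critical scores for coarser
#'   ranks are survey-specific configuration.
#' @return An object of class `assignment_thresholds`.
#' @export
assignment_thresholds <- function(species_min = 95, coarser = NULL) {
  stopifnot(species_min > 0, species_min <= 100)
  if (!is.null(coarser)) {
    stopifnot(all(c("rank", "min_percent") %in% names(coarser)))
    mins <- coarser$min_percent
    if (any(mins <= 0 | mins > 100) ||
        any(diff(c(species_min, mins)) >= 0)) {
      stop("coarser thresholds must be in (0, 100] and strictly decreasing ",
           "below species_min")
    }
  }
  structure(list(species_min = species_min, coarser = coarser),
            class = "assignment_thresholds")
}

#' Assign a taxonomic rank from a percent identity
#'
#' Returns `"species"` iff `identity > species_min` (strictly); otherwise
#' the finest coarser rank whose threshold is exceeded; otherwise
#' `"unassigned"`. Monotone: a higher identity never yields a coarser rank.
#'
#' @param identity Numeric vector of percent identities in `[0, 100]`.
#' @param thresholds An [assignment_thresholds()] object.
#' @return Character vector of rank labels.
#' @export
assign_rank <- function(identity, thresholds = assignment_thresholds()) {
  stopifnot(inherits(thresholds, "assignment_thresholds"),
            all(identity >= 0 & identity <= 100))
  out <- rep("unassigned", length(identity))
  if (!is.null(thresholds$coarser)) {
    for (i in rev(seq_len(nrow(thresholds$coarser)))) {
      out[identity > thresholds$coarser$min_percent[i]] <-
        thresholds$coarser$rank[i]
    }
  }
  out[identity > thresholds$species_min] <- "species"
  out
}

#' Read a tabular best-hit file
#'
#' Expects a TSV with at least the columns `query_id`, `identical_sites`
#' and `query_size` (BLAST-style identity fractions); `accession`,
#' `organism`, `family`, `order` are carried through when present.
#'
#' @param path Path to the TSV.
#' @return Data frame of validated hit records.
#' @export
read_hits_table <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("query_id", "identical_sites", "query_size")
  if (!all(need %in% names(h))) {
    stop("hits table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(h$query_size) | h$query_size <= 0 |
               !is.finite(h$identical_sites) | h$identical_sites < 0 |
               h$identical_sites > h$query_size)
  if (length(bad)) {
    stop("malformed hit record at row ", bad[1L],
         ": identical_sites/query_size invalid")
  }
  h
}

#' Best INSD hits of the riverine COI survey's GMYC species
#'
#' The bundled table of highest-similarity INSD (GenBank/ENA/DDBJ) matches
#' for the representative sequences of the 369 GMYC species delimited in a
#' riverine benthic COI metabarcoding survey (sequence data: DDBJ SRA
#' DRA012522). Columns include the identity fraction
#' (`identical_sites`/`query_size`), the printed similarity score
#' (`printed_identity`), accession, organism and lineage.
#'
#' @return Data frame with 369 rows.
#' @export
riverine_best_hits <- function() {
  read_hits_table(system.file("extdata", "insd_best_hits.tsv",
                              package = "coipipe", mustWork = TRUE))
}

#' Summarise rank-level assignments of a hit table
#'
#' Computes each hit's percent identity, assigns a rank, and tabulates
#' per-rank counts. Record counts are conserved: the per-rank counts (plus
#' unassigned) sum to the number of hits.
#'
#' @param hits Data frame as returned by [read_hits_table()].
#' @param thresholds An [assignment_thresholds()] object.
#' @return A list with `hits` (the input plus `identity` and `rank`
#'   columns) and `counts` (named integer vector per rank, including
#'   `unassigned`).
#' @export
summarize_hits <- function(hits, thresholds = assignment_thresholds()) {
  identity <- percent_identity(hits$identical_sites, hits$query_size)
  rank <- assign_rank(identity, thresholds)
  ranks <- c("species",
             if (!is.null(thresholds$coarser)) thresholds$coarser$rank,
             "unassigned")
  counts <- vapply(ranks, function(r) sum(rank == r), integer(1))
  hits$identity <- identity
  hits$rank <- rank
  list(hits = hits, counts = counts)
}
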