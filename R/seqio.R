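# Sequence IO: FASTQ read pairs, abundance-annotated FASTA, sample manifests,
# and demultiplexing of inline 8-nt sample tags.

#' Read a FASTQ file into a data frame
#'
#' Records are validated structurally first, so malformed input is reported
#' with the offending line number; parsing is then delegated to
#' \pkg{Biostrings}.
#'
#' @param path Path to a FASTQ file (Phred+33).
#' @return A data.frame with character columns `id`, `seq`, `qual` (quality
#'   as a Phred+33-encoded string, same length as `seq`).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("malformed FASTQ in '", path, "': ", n,
         " lines is not a multiple of 4 (truncated record near line ", n, ")")
  }
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  at <- seq(1L, n, by = 4L)
  bad_hdr <- at[substr(lines[at], 1L, 1L) != "@"]
  if (length(bad_hdr)) {
    stop("malformed FASTQ in '", path, "': line ", bad_hdr[1L],
         " does not start with '@'")
  }
  bad_sep <- at[substr(lines[at + 2L], 1L, 1L) != "+"]
  if (length(bad_sep)) {
    stop("malformed FASTQ in '", path, "': line ", bad_sep[1L] + 2L,
         " does not start with '+'")
  }
  bad_len <- at[nchar(lines[at + 1L]) != nchar(lines[at + 3L])]
  if (length(bad_len)) {
    stop("malformed FASTQ in '", path, "': quality length differs from ",
         "sequence length at line ", bad_len[1L] + 3L)
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write reads to FASTQ
#'
#' @param reads Data frame with columns `id`, `seq`, `qual` (Phred+33 string).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

# strip common mate suffixes: "/1", "/2", and " 1:...", " 2:..." dialects
strip_mate_suffix <- function(id) {
  id <- sub("/[12]$", "", id)
  sub("\\s[12](:.*)?$", "", id)
}

#' Read paired FASTQ files as read pairs
#'
#' Forward and reverse files must list mates in matching order; mate ids must
#' agree after removing the usual `/1`,`/2` or `" 1:"`,`" 2:"` suffixes.
#'
#' @param path_fwd,path_rev FASTQ files for the forward and reverse mates.
#' @return An object of class `read_pairs`: a list with aligned data frames
#'   `fwd` and `rev` (columns `id`, `seq`, `qual`).
#' @export
read_fastq_pairs <- function(path_fwd, path_rev) {
  fwd <- read_fastq(path_fwd)
  rev <- read_fastq(path_rev)
  if (nrow(fwd) != nrow(rev)) {
    stop("pairing error: '", path_fwd, "' has ", nrow(fwd),
         " records but '", path_rev, "' has ", nrow(rev))
  }
  if (nrow(fwd) > 0) {
    mism <- which(strip_mate_suffix(fwd$id) != strip_mate_suffix(rev$id))
    if (length(mism)) {
      stop("pairing error: mate ids disagree at record ", mism[1L], " ('",
           fwd$id[mism[1L]], "' vs '", rev$id[mism[1L]], "')")
    }
  }
  read_pairs(fwd, rev)
}

#' Construct a read-pair object
#'
#' @param fwd,rev Data frames with columns `id`, `seq`, `qual`, one row per
#'   mate, in matching order.
#' @return An object of class `read_pairs`.
#' @export
read_pairs <- function(fwd, rev) {
  stopifnot(nrow(fwd) == nrow(rev))
  structure(list(fwd = fwd, rev = rev), class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) nrow(x$fwd)

#' @export
print.read_pairs <- function(x, ...) {
  cat("<read_pairs> ", length(x), " pairs\n", sep = "")
  invisible(x)
}

# row subset of a read_pairs object
pairs_subset <- function(pairs, idx) {
  read_pairs(pairs$fwd[idx, , drop = FALSE], pairs$rev[idx, , drop = FALSE])
}

#' Read a sample manifest (sample_id, tag)
#'
#' @param path TSV file with columns `sample_id` and `tag`.
#' @return A data.frame validated as a manifest: unique 8-nt tags over
#'   A/C/G/T, unique sample ids.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tag") %in% names(m))) {
    stop("manifest must have columns 'sample_id' and 'tag'")
  }
  validate_manifest(m[, c("sample_id", "tag")])
}

validate_manifest <- function(manifest) {
  if (nrow(manifest) == 0L) stop("manifest is empty")
  if (anyDuplicated(manifest$tag)) {
    stop("configuration error: duplicate tags in manifest: ",
         paste(unique(manifest$tag[duplicated(manifest$tag)]), collapse = ", "))
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop("configuration error: duplicate sample ids in manifest")
  }
  if (any(nchar(manifest$tag) != 8L) || any(grepl("[^ACGT]", manifest$tag))) {
    stop("tags must be 8-nt strings over A/C/G/T")
  }
  manifest
}

#' The eight-sample tag manifest of the riverine COI survey
#'
#' Octanucleotide indexing tags of the eight sequencing runs
#' (DDBJ SRA DRA012522, runs DRR311861-DRR311868).
#'
#' @return A data.frame with columns `sample_id` and `tag`.
#' @export
riverine_manifest <- function() {
  data.frame(
    sample_id = paste0("DRR3118", 61:68),
    tag = c("TCGACTAG", "TTCTAGCT", "CCTAGAGT", "GCGTAAGA",
            "CTATTAAG", "AAGGCTAT", "GAGCCTTA", "TTATGCGA"),
    stringsAsFactors = FALSE
  )
}

#' Demultiplex read pairs by inline forward-read tags
#'
#' A pair is assigned to sample `s` iff the first 8 bases of the forward read
#' exactly equal the tag of `s` (no mismatch tolerance); assignment removes
#' the tag bases from the forward read. Pairs matching no tag go to the
#' unassigned bin unchanged. Every input pair lands in exactly one bin.
#'
#' @param pairs A `read_pairs` object.
#' @param manifest Data frame with columns `sample_id`, `tag` (8-nt, unique).
#' @return A list with `samples` (named list of `read_pairs`, one per
#'   manifest sample, tag stripped) and `unassigned` (a `read_pairs`).
#' @export
demultiplex <- function(pairs, manifest) {
  manifest <- validate_manifest(manifest)
  tag_obs <- substr(pairs$fwd$seq, 1L, 8L)
  hit <- match(tag_obs, manifest$tag)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    idx <- which(!is.na(hit) & hit == i)
    sub <- pairs_subset(pairs, idx)
    sub$fwd$seq <- substring(sub$fwd$seq, 9L)
    sub$fwd$qual <- substring(sub$fwd$qual, 9L)
    sub
  })
  names(samples) <- manifest$sample_id
  list(samples = samples, unassigned = pairs_subset(pairs, which(is.na(hit))))
}

#' Write sequences with read counts to FASTA
#'
#' Counts are encoded in the header as the de-facto amplicon convention
#' `;size=N`.
#'
#' @param records Data frame with columns `id`, `seq` and `count`
#'   (integer; defaults to 1 when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicate ids in FASTA records")
  count <- records$count %||% rep(1L, nrow(records))
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- sprintf("%s;size=%d", records$id, as.integer(count))
  Biostrings::writeXStringSet(x, path, width = 20000L)
  invisible(path)
}

#' Read an abundance-annotated FASTA file
#'
#' Inverse of [write_fasta()]: headers of the form `id;size=N` yield the
#' `count` column; headers without a size annotation get count 1.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `id`, `seq`, `count`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  has_size <- grepl(";size=\\d+$", hdr)
  count <- rep(1L, length(hdr))
  count[has_size] <- as.integer(sub("^.*;size=(\\d+)$", "\\1", hdr[has_size]))
  id <- ifelse(has_size, sub(";size=\\d+$", "", hdr), hdr)
  data.frame(id = id, seq = as.character(x), count = count,
             stringsAsFactors = FALSE, row.names = NULL)
}
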