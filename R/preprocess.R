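# Read preprocessing: quality filtering, IUPAC-aware primer trimming,
# paired-end overlap merging, and fixed-length selection.

#' Amplicon-specific COI primer pair (Leray fragment)
#'
#' The amplicon-specific parts of the tailed PCR primers used for the 313 bp
#' mitochondrial COI fragment: mlCOIintF-type forward and jgHCO2198-type
#' reverse, both with IUPAC degeneracies.
#'
#' @return A list with elements `fwd` and `rev` (IUPAC strings).
#' @export
default_primers <- function() {
  list(fwd = "GGWACWGGWTGAACWGTWTAYCCYCC",
       rev = "TAHACTTCNGGGTGKCCRAARAATCA")
}

validate_primers <- function(primers) {
  stopifnot(is.list(primers), all(c("fwd", "rev") %in% names(primers)))
  for (p in c(primers$fwd, primers$rev)) {
    if (grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), p)) {
      stop("primer contains characters outside the IUPAC nucleotide alphabet: ", p)
    }
  }
  primers
}

#' Preprocessing configuration
#'
#' @param min_quality Phred threshold for the quality filter (default 20).
#' @param quality_policy How the threshold is applied per mate: `"mean"`
#'   (default; discard if the mate's mean Phred is below the threshold),
#'   `"min"` (discard if any base is below), or `"window"` (discard if any
#'   sliding window of `window_width` bases has mean below).
#' @param window_width Width of the sliding window for the `"window"`
#'   policy (default 25).
#' @param target_length Net amplicon length retained by [length_select()]
#'   (default 313).
#' @param min_overlap Minimum acceptable mate overlap in [merge_pairs()]
#'   (default 20).
#' @param max_overlap_mismatch_frac Maximum fraction of mismatching bases
#'   tolerated in the chosen overlap (default 0.1).
#' @param drop_n Remove merged amplicons containing N (default TRUE).
#' @param max_primer_mismatch Maximum IUPAC-aware mismatches when locating a
#'   primer (default 2).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_quality = 20,
                          quality_policy = c("mean", "min", "window"),
                          window_width = 25L,
                          target_length = 313L,
                          min_overlap = 20L,
                          max_overlap_mismatch_frac = 0.1,
                          drop_n = TRUE,
                          max_primer_mismatch = 2L) {
  quality_policy <- match.arg(quality_policy)
  stopifnot(min_quality > 0, target_length > 0, min_overlap > 0,
            window_width > 0,
            max_overlap_mismatch_frac >= 0, max_overlap_mismatch_frac <= 1)
  structure(list(min_quality = min_quality, quality_policy = quality_policy,
                 window_width = as.integer(window_width),
                 target_length = as.integer(target_length),
                 min_overlap = as.integer(min_overlap),
                 max_overlap_mismatch_frac = max_overlap_mismatch_frac,
                 drop_n = isTRUE(drop_n),
                 max_primer_mismatch = as.integer(max_primer_mismatch)),
            class = "filter_config")
}

#' IUPAC-aware base match
#'
#' Is an observed base compatible with a (possibly degenerate) pattern base?
#' `N` in the pattern matches every observed base; an observed `N` matches
#' only a fully degenerate pattern base (`N`).
#'
#' @param pattern_base Character vector of IUPAC codes.
#' @param observed_base Character vector over A/C/G/T/N (recycled with
#'   `pattern_base`).
#' @return Logical vector.
#' @export
#' @examples
#' iupac_match("W", c("A", "C"))  # TRUE FALSE
iupac_match <- function(pattern_base, observed_base) {
  n <- max(length(pattern_base), length(observed_base))
  pattern_base <- rep_len(toupper(pattern_base), n)
  observed_base <- rep_len(toupper(observed_base), n)
  bad <- !(pattern_base %in% names(IUPAC_SETS))
  if (any(bad)) {
    stop("invalid IUPAC code in pattern: ",
         paste(unique(pattern_base[bad]), collapse = ", "))
  }
  mapply(function(p, o) {
    if (o == "N") return(p == "N")
    o %in% IUPAC_SETS[[p]]
  }, pattern_base, observed_base, USE.NAMES = FALSE)
}

# number of IUPAC-aware mismatches between a pattern and an observed string
# of the same length (vectorised over observed strings)
iupac_mismatches <- function(pattern, observed) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sets <- IUPAC_SETS[pat]
  vapply(strsplit(observed, "", fixed = TRUE), function(obs) {
    sum(!mapply(function(s, o) if (o == "N") identical(s, IUPAC_SETS$N) else o %in% s,
                sets, obs))
  }, integer(1))
}

#' Quality-filter read pairs
#'
#' Applies the per-mate Phred rule of `cfg$quality_policy`: under `"mean"`
#' (default) a pair is discarded iff the mean Phred of either mate is below
#' `cfg$min_quality`; under `"min"`, iff any base of either mate is below;
#' under `"window"`, iff any sliding window's mean is below.
#'
#' @param pairs A `read_pairs` object with qualities on both mates.
#' @param cfg A [filter_config()].
#' @return Logical vector, `TRUE` for pairs to keep.
#' @export
quality_filter <- function(pairs, cfg = filter_config()) {
  if (any(!nzchar(pairs$fwd$qual)) || any(!nzchar(pairs$rev$qual))) {
    stop("quality_filter requires Phred qualities on both mates")
  }
  mate_ok <- function(qual) {
    q <- phred_decode(qual)
    switch(cfg$quality_policy,
      mean = vapply(q, mean, numeric(1)) >= cfg$min_quality,
      min = vapply(q, min, numeric(1)) >= cfg$min_quality,
      window = vapply(q, function(v) {
        w <- min(cfg$window_width, length(v))
        cs <- cumsum(c(0, v))
        means <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
        min(means) >= cfg$min_quality
      }, logical(1))
    )
  }
  mate_ok(pairs$fwd$qual) & mate_ok(pairs$rev$qual)
}

#' Trim primers from a sequence
#'
#' Locates the forward primer as a prefix and/or the reverse complement of
#' the reverse primer as a suffix, allowing up to `max_mismatch` IUPAC-aware
#' mismatches at each site, and returns the insert between the located
#' sites. `ends` selects which sites are required: `"both"` for a merged
#' amplicon, `"fwd"` for a forward mate (5' forward primer only), `"rev"`
#' for a reverse mate, whose 5' end carries the reverse primer as
#' synthesised.
#'
#' @param seq Character vector of sequences (A/C/G/T/N).
#' @param qual Optional character vector of Phred+33 strings trimmed in
#'   step with `seq`.
#' @param primers List with IUPAC strings `fwd` and `rev` (see
#'   [default_primers()]).
#' @param max_mismatch Maximum IUPAC-aware mismatches per primer site
#'   (default 2).
#' @param ends One of `"both"`, `"fwd"`, `"rev"`.
#' @return A list with `seq`, `qual` (trimmed; `NA` where rejected) and
#'   logical `keep`.
#' @export
trim_primers <- function(seq, qual = NULL, primers = default_primers(),
                         max_mismatch = 2L, ends = c("both", "fwd", "rev")) {
  ends <- match.arg(ends)
  primers <- validate_primers(primers)
  n <- length(seq)
  keep <- rep(TRUE, n)
  from <- rep(1L, n)
  to <- nchar(seq)

  if (ends %in% c("both", "fwd")) {
    p <- primers$fwd
    long_enough <- nchar(seq) >= nchar(p)
    mm <- rep(Inf, n)
    mm[long_enough] <- iupac_mismatches(p, substr(seq[long_enough], 1L, nchar(p)))
    ok <- long_enough & mm <= max_mismatch
    keep <- keep & ok
    from <- pmax(from, nchar(p) + 1L)
  }
  if (ends == "rev") {
    p <- primers$rev
    long_enough <- nchar(seq) >= nchar(p)
    mm <- rep(Inf, n)
    mm[long_enough] <- iupac_mismatches(p, substr(seq[long_enough], 1L, nchar(p)))
    keep <- keep & long_enough & mm <= max_mismatch
    from <- pmax(from, nchar(p) + 1L)
  }
  if (ends == "both") {
    p <- revcomp(primers$rev)
    long_enough <- to - from + 1L >= nchar(p)
    mm <- rep(Inf, n)
    mm[long_enough] <- iupac_mismatches(p,
      substr(seq[long_enough], to[long_enough] - nchar(p) + 1L, to[long_enough]))
    keep <- keep & long_enough & mm <= max_mismatch
    to <- to - nchar(p)
  }

  out_seq <- ifelse(keep, substr(seq, from, to), NA_character_)
  out_qual <- if (!is.null(qual)) ifelse(keep, substr(qual, from, to), NA_character_)
  list(seq = out_seq, qual = out_qual, keep = keep)
}

#' Trim primers from both mates of read pairs
#'
#' Removes the forward primer from the 5' end of forward mates and the
#' reverse primer from the 5' end of reverse mates (primers are trimmed
#' before merging).
#'
#' @param pairs A `read_pairs` object (tags already removed).
#' @inheritParams trim_primers
#' @return A list with `pairs` (trimmed `read_pairs` of the retained reads)
#'   and logical `keep` over the input pairs.
#' @export
trim_read_pairs <- function(pairs, primers = default_primers(), max_mismatch = 2L) {
  tf <- trim_primers(pairs$fwd$seq, pairs$fwd$qual, primers, max_mismatch, "fwd")
  tr <- trim_primers(pairs$rev$seq, pairs$rev$qual, primers, max_mismatch, "rev")
  keep <- tf$keep & tr$keep
  fwd <- data.frame(id = pairs$fwd$id[keep], seq = tf$seq[keep],
                    qual = tf$qual[keep], stringsAsFactors = FALSE)
  rev <- data.frame(id = pairs$rev$id[keep], seq = tr$seq[keep],
                    qual = tr$qual[keep], stringsAsFactors = FALSE)
  list(pairs = read_pairs(fwd, rev), keep = keep)
}

# merge one mate pair; f/r are lists with seq (char), qual (int vector).
# Returns list(seq, qual, overlap) or NULL when rejected.
merge_one <- function(fseq, fqual, rseq, rqual, min_overlap, max_mm_frac) {
  rc <- revcomp(rseq)
  rq <- rev(rqual)
  fi <- utf8ToInt(fseq)
  ri <- utf8ToInt(rc)
  lf <- length(fi)
  lr <- length(ri)
  if (min(lf, lr) < min_overlap) return(NULL)
  best_o <- 0L
  best_matches <- -1L
  # scan overlaps descending; matches(o) <= o lets us stop early
  for (o in seq(min(lf, lr), min_overlap)) {
    if (best_matches >= o) break
    m <- sum(fi[(lf - o + 1L):lf] == ri[1L:o])
    if (m > best_matches) {
      best_matches <- m
      best_o <- o
    }
  }
  if (best_o < min_overlap) return(NULL)
  if ((best_o - best_matches) / best_o > max_mm_frac) return(NULL)
  o <- best_o
  f_idx <- (lf - o + 1L):lf
  r_idx <- 1L:o
  f_over <- fi[f_idx]
  r_over <- ri[r_idx]
  fq_over <- fqual[f_idx]
  rq_over <- rq[r_idx]
  # higher Phred wins in the overlap (ties favour the forward mate);
  # consensus quality is the max of the two
  take_rev <- r_over != f_over & rq_over > fq_over
  cons <- ifelse(take_rev, r_over, f_over)
  cons_q <- pmax(fq_over, rq_over)
  seq <- intToUtf8(c(fi[seq_len(lf - o)], cons, ri[-(1L:o)]))
  qual <- c(fqual[seq_len(lf - o)], cons_q, rq[-(1L:o)])
  list(seq = seq, qual = qual, overlap = o)
}

#' Merge read pairs into amplicons
#'
#' The reverse mate is reverse-complemented and the ungapped overlap with
#' the forward mate that maximises the number of matching bases is chosen
#' (ties broken towards the longer overlap). A pair is rejected when the
#' best overlap is shorter than `cfg$min_overlap` or its mismatch fraction
#' exceeds `cfg$max_overlap_mismatch_frac`. In the overlap the base with the
#' higher Phred score wins and the consensus quality is the maximum of the
#' two; merged length is `len(fwd) + len(rev) - overlap`.
#'
#' @param pairs A `read_pairs` object.
#' @param cfg A [filter_config()].
#' @return A data.frame of merged amplicons with columns `id`, `seq`,
#'   `qual`, `length`, `overlap`; rejected pairs are dropped.
#' @export
merge_pairs <- function(pairs, cfg = filter_config()) {
  n <- length(pairs)
  fq <- phred_decode(pairs$fwd$qual)
  rq <- phred_decode(pairs$rev$qual)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- merge_one(pairs$fwd$seq[i], fq[[i]], pairs$rev$seq[i], rq[[i]],
                          cfg$min_overlap, cfg$max_overlap_mismatch_frac)
  }
  keep <- !vapply(out, is.null, logical(1))
  data.frame(
    id = pairs$fwd$id[keep],
    seq = vapply(out[keep], `[[`, character(1), "seq"),
    qual = phred_encode(lapply(out[keep], `[[`, "qual")),
    length = vapply(out[keep], function(x) nchar(x$seq), integer(1)),
    overlap = vapply(out[keep], `[[`, integer(1), "overlap"),
    stringsAsFactors = FALSE
  )
}

#' Select amplicons of the target net length
#'
#' Retains exactly the amplicons whose length equals `target_length`
#' (a single fixed length, not a range), preserving order; when
#' `cfg$drop_n` is set, amplicons containing N are also removed.
#'
#' @param amplicons Data frame with columns `seq` (and optionally `length`).
#' @param cfg A [filter_config()]; `cfg$target_length` is the retained length.
#' @return The retained subset of `amplicons`.
#' @export
length_select <- function(amplicons, cfg = filter_config()) {
  if (nrow(amplicons) == 0L) return(amplicons)
  len <- amplicons$length %||% nchar(amplicons$seq)
  keep <- len == cfg$target_length
  if (cfg$drop_n) keep <- keep & !grepl("N", amplicons$seq, fixed = TRUE)
  amplicons[keep, , drop = FALSE]
}
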