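# Core clustering algorithm: dereplication at 100% identity, low-count
# discard, and abundance-aware merging of unique sequences at Hamming
# distance 1 into OTUs.

#' Construct a set of unique sequence groups
#'
#' @param seq Character vector of distinct, equal-length sequences.
#' @param count Integer read counts (>= 1), one per sequence.
#' @param sample_counts Optional integer matrix (rows = groups, columns =
#'   samples); row sums must equal `count`.
#' @return An object of class `unique_groups`.
#' @export
unique_groups <- function(seq, count, sample_counts = NULL) {
  stopifnot(length(seq) == length(count), all(count >= 1))
  if (anyDuplicated(seq)) stop("unique_groups requires distinct sequences")
  if (length(seq) && length(unique(nchar(seq))) > 1L) {
    stop("sequences have mixed lengths")
  }
  if (!is.null(sample_counts)) {
    sample_counts <- as.matrix(sample_counts)
    if (nrow(sample_counts) != length(seq) ||
        !isTRUE(all.equal(unname(rowSums(sample_counts)), as.numeric(count)))) {
      stop("sample_counts row sums must equal count")
    }
  }
  structure(list(seq = seq, count = as.integer(count),
                 sample_counts = sample_counts),
            class = "unique_groups")
}

#' @export
length.unique_groups <- function(x) length(x$seq)

#' @export
print.unique_groups <- function(x, ...) {
  cat("<unique_groups> ", length(x), " unique sequences, ",
      sum(x$count), " reads\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.unique_groups <- function(x, ...) {
  df <- data.frame(seq = x$seq, count = x$count, stringsAsFactors = FALSE)
  if (!is.null(x$sample_counts)) df <- cbind(df, as.data.frame(x$sample_counts))
  df
}

groups_subset <- function(x, idx) {
  unique_groups(x$seq[idx], x$count[idx],
                if (!is.null(x$sample_counts)) x$sample_counts[idx, , drop = FALSE])
}

#' Dereplicate amplicons at 100% identity
#'
#' Collapses identical sequences into unique groups with read counts
#' (overall and per sample), sorted by descending count with ties broken
#' lexicographically by sequence.
#'
#' @param seq Character vector of equal-length amplicon sequences (one
#'   element per read), or a data.frame with a `seq` column.
#' @param sample Optional character vector of sample labels, one per read.
#' @return A [unique_groups()] object; total counts are conserved.
#' @export
dereplicate <- function(seq, sample = NULL) {
  if (is.data.frame(seq)) {
    if (is.null(sample) && !is.null(seq$sample)) sample <- seq$sample
    seq <- seq$seq
  }
  if (length(seq) == 0L) return(unique_groups(character(0), integer(0)))
  if (length(unique(nchar(seq))) > 1L) stop("sequences have mixed lengths")
  tab <- table(seq)
  us <- names(tab)
  count <- as.integer(tab)
  ord <- order(-count, us)
  sc <- NULL
  if (!is.null(sample)) {
    stopifnot(length(sample) == length(seq))
    sc <- unclass(table(seq, sample))
    sc <- matrix(as.integer(sc), nrow = nrow(sc),
                 dimnames = dimnames(sc))[match(us, rownames(sc)), , drop = FALSE]
  }
  unique_groups(us[ord], count[ord],
                if (!is.null(sc)) sc[ord, , drop = FALSE])
}

#' Discard low-abundance groups
#'
#' Retains groups whose total read count is at least `min_group_count`
#' (default 3: groups of fewer than three reads are discarded), preserving
#' order.
#'
#' @param groups A [unique_groups()] object.
#' @param min_group_count Minimum total count to retain (default 3).
#' @return The retained [unique_groups()].
#' @export
abundance_filter <- function(groups, min_group_count = 3L) {
  stopifnot(inherits(groups, "unique_groups"), min_group_count >= 1)
  groups_subset(groups, which(groups$count >= min_group_count))
}

#' Find all pairs of sequences at Hamming distance 1
#'
#' Uses masked-position hashing: for each position, sequences are bucketed
#' by the string with that position deleted; members of a bucket differ
#' exactly at the masked position. A pair at distance 1 lands in exactly one
#' bucket, so no all-pairs scan (and no deduplication) is needed.
#'
#' @param x A [unique_groups()] object or a character vector of distinct
#'   equal-length sequences.
#' @return A 2-column integer matrix of index pairs (`i < j`), one row per
#'   pair at Hamming distance exactly 1.
#' @export
hamming1_neighbors <- function(x) {
  seqs <- if (inherits(x, "unique_groups")) x$seq else x
  n <- length(seqs)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (n < 2L) return(empty)
  if (length(unique(nchar(seqs))) > 1L) stop("sequences have mixed lengths")
  if (anyDuplicated(seqs)) stop("sequences must be distinct (dereplicate first)")
  L <- nchar(seqs[1L])
  pairs <- vector("list", L)
  for (p in seq_len(L)) {
    key <- paste0(substr(seqs, 1L, p - 1L), substr(seqs, p + 1L, L))
    if (!anyDuplicated(key)) next
    dup <- unique(key[duplicated(key)])
    idx <- which(key %in% dup)
    buckets <- split(idx, key[idx])
    pairs[[p]] <- do.call(rbind, lapply(buckets, function(b) {
      b <- sort(b)
      m <- t(utils::combn(b, 2L))
      m
    }))
  }
  out <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Cluster unique groups into OTUs by single-nucleotide differences
#'
#' Under the default `"abundance_greedy"` policy, groups are visited in
#' descending read count (ties lexicographic by sequence); each group joins
#' the OTU of its highest-count already-assigned Hamming-1 neighbour whose
#' count is at least its own, or founds a new OTU. Chains of single-mismatch
#' neighbours therefore merge transitively, but only downhill in abundance,
#' which is what lets sequencing-error satellites be absorbed by their
#' parent haplotype while genuine co-abundant haplotypes stay apart. Under
#' `"connected_components"`, OTUs are simply the connected components of
#' the Hamming-1 graph; the greedy partition always refines it.
#'
#' @param groups A [unique_groups()] object, already abundance-filtered.
#' @param min_group_count The filter floor the input must satisfy
#'   (default 3); a group below it is a contract violation and an error.
#' @param method `"abundance_greedy"` (default) or `"connected_components"`.
#' @return An object of class `otu_set`: list with `otus` (data.frame
#'   `otu_id`, `representative`, `total_count`, `n_members`), `members`
#'   (data.frame `otu_id`, `seq`, `count`), the input `groups` (reordered),
#'   and `method`.
#' @export
cluster_otus <- function(groups, min_group_count = 3L,
                         method = c("abundance_greedy", "connected_components")) {
  method <- match.arg(method)
  stopifnot(inherits(groups, "unique_groups"))
  if (any(groups$count < min_group_count)) {
    stop("contract violation: groups below min_group_count = ", min_group_count,
         " present; run abundance_filter() first")
  }
  ord <- order(-groups$count, groups$seq)
  g <- groups_subset(groups, ord)
  n <- length(g)
  nb <- hamming1_neighbors(g)
  otu_of <- integer(n)
  if (n > 0L) {
    adj <- split(c(nb[, 2L], nb[, 1L]), c(nb[, 1L], nb[, 2L]))
    if (method == "abundance_greedy") {
      n_otus <- 0L
      for (i in seq_len(n)) {
        cand <- adj[[as.character(i)]]
        cand <- cand[cand < i]  # already assigned => count >= own (sort order)
        if (length(cand)) {
          # highest-count neighbour; ties by sort order (lexicographic)
          best <- min(cand[g$count[cand] == max(g$count[cand])])
          otu_of[i] <- otu_of[best]
        } else {
          n_otus <- n_otus + 1L
          otu_of[i] <- n_otus
        }
      }
    } else {
      # connected components of the Hamming-1 graph (union-find)
      parent <- seq_len(n)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (r in seq_len(nrow(nb))) {
        a <- find(nb[r, 1L]); b <- find(nb[r, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(n), find, integer(1))
      otu_of <- match(roots, unique(roots))  # numbered by first (highest) member
    }
  }
  build_otu_set(g, otu_of, method, min_group_count)
}

build_otu_set <- function(g, otu_of, method, min_group_count) {
  n_otus <- if (length(otu_of)) max(otu_of, 0L) else 0L
  width <- max(3L, nchar(as.character(n_otus)))
  ids <- sprintf(paste0("OTU_%0", width, "d"), otu_of)
  reps <- integer(n_otus)
  for (k in seq_len(n_otus)) {
    mem <- which(otu_of == k)
    reps[k] <- mem[order(-g$count[mem], g$seq[mem])][1L]
  }
  otus <- data.frame(
    otu_id = sprintf(paste0("OTU_%0", width, "d"), seq_len(n_otus)),
    representative = g$seq[reps],
    total_count = as.integer(vapply(seq_len(n_otus),
                                    function(k) sum(g$count[otu_of == k]), numeric(1))),
    n_members = as.integer(tabulate(otu_of, n_otus)),
    stringsAsFactors = FALSE
  )
  structure(list(
    otus = otus,
    members = data.frame(otu_id = ids, seq = g$seq, count = g$count,
                         stringsAsFactors = FALSE),
    groups = g, otu_of = otu_of, method = method,
    min_group_count = min_group_count
  ), class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat("<otu_set> ", nrow(x$otus), " OTUs from ", length(x$groups),
      " unique groups (", sum(x$groups$count), " reads), method = ",
      x$method, "\n", sep = "")
  invisible(x)
}

#' @export
summary.otu_set <- function(object, ...) {
  cat("OTU clustering (", object$method, ", min group count ",
      object$min_group_count, ")\n", sep = "")
  cat("  unique groups: ", length(object$groups), "\n", sep = "")
  cat("  OTUs:          ", nrow(object$otus), "\n", sep = "")
  cat("  reads:         ", sum(object$otus$total_count), "\n", sep = "")
  invisible(object)
}

#' Representative sequence of an OTU
#'
#' The member with the largest read count; ties are broken
#' lexicographically by sequence, so the choice is deterministic.
#'
#' @param members Data frame with columns `seq` and `count` (the members of
#'   one OTU).
#' @return The single representative row of `members`.
#' @export
select_representative <- function(members) {
  if (nrow(members) == 0L) stop("empty OTU has no representative")
  members[order(-members$count, members$seq)[1L], , drop = FALSE]
}

#' OTU-by-sample count table
#'
#' @param x An `otu_set` whose groups carry per-sample counts (from
#'   [dereplicate()] with sample labels). Without sample labels a single
#'   column `total` is returned.
#' @return Integer matrix, rows = OTU ids, columns = samples; row sums
#'   equal the OTU total counts.
#' @export
otu_table <- function(x) {
  stopifnot(inherits(x, "otu_set"))
  n_otus <- nrow(x$otus)
  sc <- x$groups$sample_counts
  if (is.null(sc)) {
    sc <- matrix(x$groups$count, ncol = 1, dimnames = list(NULL, "total"))
  }
  out <- matrix(0L, nrow = n_otus, ncol = ncol(sc),
                dimnames = list(x$otus$otu_id, colnames(sc)))
  for (k in seq_len(n_otus)) {
    out[k, ] <- as.integer(colSums(sc[x$otu_of == k, , drop = FALSE]))
  }
  out
}
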