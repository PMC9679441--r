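# Fixture builders and independent oracles shared across test files.
# Oracles here are deliberately naive (all-pairs scans, direct traversals)
# so they stay independent of the package's optimised code paths.

# canonical form of a tip partition: sorted vector of sorted,
# comma-joined blocks (names dropped, so labels do not matter)
norm_partition <- function(p) {
  sort(unname(vapply(p, function(x) paste(sort(x), collapse = ","),
                     character(1))))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_at <- function(seq, pos, base = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- if (is.null(base)) sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1) else base
  paste(ch, collapse = "")
}

# structured clustering instance: seed sequences spawn distance-1 children
# (and occasional grandchildren), so the Hamming-1 graph has real edges.
# Returns a unique_groups object with all counts >= 3.
make_otu_instance <- function(seed, n_seeds = 8, len = 40, max_children = 4) {
  set.seed(seed)
  seqs <- character(0)
  counts <- integer(0)
  for (i in seq_len(n_seeds)) {
    parent <- random_dna(1, len)
    if (parent %in% seqs) next
    pc <- sample(50:500, 1)
    seqs <- c(seqs, parent)
    counts <- c(counts, pc)
    for (k in seq_len(sample(0:max_children, 1))) {
      child <- mutate_at(parent, sample(len, 1))
      if (child %in% seqs) next
      cc <- max(3L, as.integer(pc / sample(10:50, 1)))
      seqs <- c(seqs, child)
      counts <- c(counts, cc)
      if (runif(1) < 0.3) {
        gc <- mutate_at(child, sample(len, 1))
        if (!(gc %in% seqs)) {
          seqs <- c(seqs, gc)
          counts <- c(counts, 3L)
        }
      }
    }
  }
  unique_groups(seqs, counts)
}

# all-pairs Hamming-1 edge list (oracle for masked-position hashing)
brute_hamming1 <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = n, byrow = TRUE)
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- colSums(t(mat[(i + 1):n, , drop = FALSE]) != mat[i, ])
    js <- which(d == 1) + i
    if (length(js)) out[[length(out) + 1]] <- cbind(i, js)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) matrix(integer(0), ncol = 2) else unname(m)
}

# connected components of an edge list by breadth-first search (oracle)
brute_components <- function(n, edges) {
  comp <- rep(NA_integer_, n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  k <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# pure single-process log-likelihood computed directly from branching
# times (oracle for the model-collapse identities)
direct_single_process <- function(tree, lambda, p, coalescent) {
  bt <- sort(branching_times(tree))
  n <- length(bt) + 1
  x <- diff(c(0, bt))
  L <- n:2
  unit <- if (coalescent) (L * (L - 1))^p else L^p
  sum(log(lambda * unit) - lambda * unit * x)
}

# partition implied by a gmyc fit / membership table
entities_partition <- function(df, key) split(df$tip, df[[key]])
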