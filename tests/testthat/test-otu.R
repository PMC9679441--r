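test_that("dereplication counts identical sequences and sorts deterministically", {
  g <- dereplicate(c("ACG", "ACG", "ACT"))
  expect_equal(g$seq, c("ACG", "ACT"))
  expect_equal(g$count, c(2L, 1L))
  expect_equal(length(dereplicate(character(0))), 0L)
  expect_error(dereplicate(c("AC", "ACG")), "mixed lengths")

  # against an independent hash-table tally on noisy simulated reads
  set.seed(3)
  haps <- random_dna(20, 50)
  reads <- haps[sample(20, 10000, replace = TRUE)]
  flip <- runif(10000) < 0.05
  reads[flip] <- vapply(reads[flip], function(s) mutate_at(s, sample(50, 1)),
                        character(1))
  g <- dereplicate(reads)
  tally <- new.env()
  for (r in reads) {
    assign(r, get0(r, envir = tally, ifnotfound = 0L) + 1L, envir = tally)
  }
  expect_equal(length(g), length(ls(tally)))
  expect_equal(sum(g$count), 10000L)
  for (i in sample(length(g), 50)) {
    expect_equal(g$count[i], get(g$seq[i], tally))
  }
  # ordering: count descending, ties lexicographic
  expect_true(all(diff(g$count) <= 0))
  ties <- split(g$seq, g$count)
  expect_true(all(vapply(ties, function(s) !is.unsorted(s), logical(1))))
})

test_that("per-sample counts are carried through dereplication", {
  g <- dereplicate(c("AAA", "AAA", "CCC"), sample = c("s1", "s2", "s1"))
  expect_equal(g$sample_counts[g$seq == "AAA", ], c(s1 = 1L, s2 = 1L))
  expect_equal(unname(rowSums(g$sample_counts)), g$count)
})

test_that("abundance filter keeps groups at or above the floor, in order", {
  g <- unique_groups(c("AAAA", "CCCC", "GGGG", "TTTT"), c(5L, 3L, 2L, 1L))
  expect_equal(abundance_filter(g, 3)$count, c(5L, 3L))
  expect_equal(abundance_filter(g, 1)$count, g$count)  # identity at floor 1
  set.seed(7)
  cnt <- sample(1:20, 100, replace = TRUE)
  gg <- unique_groups(random_dna(100, 30), cnt)
  for (m in c(1, 3, 7)) {
    expect_equal(abundance_filter(gg, m)$count, cnt[cnt >= m])
  }
})

test_that("masked-position hashing finds exactly the Hamming-1 pairs", {
  expect_equal(nrow(hamming1_neighbors(c("AAAA", "AAAT"))), 1L)
  expect_equal(nrow(hamming1_neighbors(c("AAAA", "AATT"))), 0L)
  expect_error(hamming1_neighbors(c("AAAA", "AAAA")), "distinct")

  set.seed(11)
  # structured pool (real edges) plus random 313-nt background
  inst <- make_otu_instance(11, n_seeds = 30, len = 313)
  seqs <- unique(c(inst$seq, random_dna(400, 313)))
  got <- hamming1_neighbors(seqs)
  want <- brute_hamming1(seqs)
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
               ignore_attr = TRUE)
})

test_that("the abundance-greedy rule follows its trace on a hand-built chain", {
  # A:100 - B:10 - C:5 with d(A,B)=1, d(B,C)=1, d(A,C)=2: one OTU of 115
  A <- strrep("A", 10)
  B <- mutate_at(A, 1, "C")
  C <- mutate_at(B, 2, "G")
  g <- unique_groups(c(A, B, C), c(100L, 10L, 5L))
  res <- cluster_otus(g, min_group_count = 3)
  expect_equal(nrow(res$otus), 1L)
  expect_equal(res$otus$total_count, 115L)
  expect_equal(res$otus$representative, A)
  # identical under the connected-components policy
  cc <- cluster_otus(g, min_group_count = 3, method = "connected_components")
  expect_equal(cc$otus$total_count, 115L)

  # far-apart groups stay separate
  D <- strrep("T", 10)
  g2 <- unique_groups(c(A, D), c(100L, 50L))
  expect_equal(nrow(cluster_otus(g2, 3)$otus), 2L)

  # a group below the floor is a contract violation
  g3 <- unique_groups(c(A, B), c(100L, 2L))
  expect_error(cluster_otus(g3, 3), "contract violation")
})

test_that("greedy partitions refine connected components and conserve reads", {
  for (seed in c(2, 5, 19, 31)) {
    g <- make_otu_instance(seed, n_seeds = 40)
    greedy <- cluster_otus(g, 3)
    cc <- cluster_otus(g, 3, method = "connected_components")
    # read conservation
    expect_equal(sum(greedy$otus$total_count), sum(g$count))
    expect_equal(sum(cc$otus$total_count), sum(g$count))
    # oracle equality for connected components
    oracle <- brute_components(length(greedy$groups),
                               brute_hamming1(greedy$groups$seq))
    expect_equal(norm_partition(split(greedy$groups$seq, oracle)),
                 norm_partition(split(cc$members$seq, cc$members$otu_id)))
    # refinement: each greedy OTU lies inside one component
    comp_of <- oracle[match(greedy$members$seq, greedy$groups$seq)]
    expect_true(all(vapply(split(comp_of, greedy$members$otu_id),
                           function(v) length(unique(v)) == 1L, logical(1))))
    # no two groups at Hamming distance >= 2 are merged directly (pairwise
    # check inside small OTUs)
    small <- names(which(table(greedy$members$otu_id) == 2))
    for (o in small) {
      mem <- greedy$members$seq[greedy$members$otu_id == o]
      expect_equal(hamming(mem[1], mem[2]), 1L)
    }
  }
})

test_that("representatives are the most abundant member with lexicographic ties", {
  m <- data.frame(seq = c("TTTT", "AAAA"), count = c(100L, 10L))
  expect_equal(select_representative(m)$seq, "TTTT")
  expect_equal(select_representative(m[2, ])$seq, "AAAA")  # singleton
  tie <- data.frame(seq = c("GGGG", "CCCC"), count = c(5L, 5L))
  expect_equal(select_representative(tie)$seq, "CCCC")
  expect_error(select_representative(m[0, ]), "empty")
})

test_that("the OTU table sums member sample counts and matches OTU totals", {
  g <- dereplicate(c(rep("AAAA", 3), rep("AAAT", 4)),
                   sample = c("s1", "s1", "s1", "s2", "s2", "s2", "s2"))
  res <- cluster_otus(g, 3)
  tab <- otu_table(res)
  expect_equal(dim(tab), c(1L, 2L))
  expect_equal(unname(tab[1, ]), c(3L, 4L))
  expect_equal(unname(rowSums(tab)), res$otus$total_count)

  # simulator end-to-end: table row sums equal truth tallies after filtering
  sim <- generate_community(community_spec(n_haplotypes = 4, n_read_pairs = 400,
                                           per_base_error_rate = 0,
                                           length_variant_frac = 0, seed = 17))
  res <- run_pipeline(sim$pairs)
  tab <- otu_table(res$otus)
  truth_tally <- table(sim$truth$haplotype[sim$truth$tag_intact])
  hap_of_rep <- sim$haplotypes$haplotype[match(res$otus$otus$representative,
                                               sim$haplotypes$seq)]
  expect_equal(unname(rowSums(tab)),
               as.integer(truth_tally[hap_of_rep]))
})
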