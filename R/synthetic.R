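# Simulators: mock-community paired reads with the 2-step-PCR library
# layout (tag + primer + insert), and Yule-over-coalescent gene trees with
# known species membership. Everything is reproducible from the spec seed,
# so truth tables support exact precision/recall accounting downstream.

random_seq <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

# realise a degenerate IUPAC primer into a concrete A/C/G/T sequence
realize_primer <- function(primer) {
  ch <- strsplit(primer, "", fixed = TRUE)[[1]]
  paste(vapply(IUPAC_SETS[ch], function(s) s[sample.int(length(s), 1L)],
               character(1)), collapse = "")
}

#' Specification of a simulated mock community
#'
#' Defaults describe a small benthic-style community: a handful of 313-nt
#' COI haplotypes at least 5 substitutions apart, log-normally skewed
#' abundances, a low per-base substitution error rate, 2 x 300 reads laid
#' out as inline 8-nt tag + degenerate primer + insert, and a small
#' fraction of off-length (313 +/- 1) contaminant templates.
#'
#' @param n_haplotypes Number of true haplotypes (default 10).
#' @param haplotype_length Insert length in nt (default 313).
#' @param min_pairwise_distance Minimum pairwise Hamming distance enforced
#'   between haplotypes (default 5; must be >= 2).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters
#'   (defaults 0 and 1).
#' @param per_base_error_rate Substitution error probability per base
#'   (default 0.002; indels are not modelled).
#' @param n_read_pairs Total read pairs to simulate (default 1000).
#' @param read_length Read length (default 300).
#' @param length_variant_frac Fraction of reads drawn from a
#'   single-deletion length variant of their haplotype (default 0.05).
#' @param primers Primer pair, as [default_primers()].
#' @param tags Sample manifest (default [riverine_manifest()]).
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_haplotypes = 10L, haplotype_length = 313L,
                           min_pairwise_distance = 5L,
                           abundance_meanlog = 0, abundance_sdlog = 1,
                           per_base_error_rate = 0.002,
                           n_read_pairs = 1000L, read_length = 300L,
                           length_variant_frac = 0.05,
                           primers = default_primers(),
                           tags = riverine_manifest(), seed) {
  stopifnot(min_pairwise_distance >= 2, per_base_error_rate >= 0,
            per_base_error_rate <= 1, length_variant_frac >= 0,
            length_variant_frac <= 1, n_haplotypes >= 1, n_read_pairs >= 0)
  if (missing(seed)) stop("community_spec requires a seed")
  structure(as.list(environment()), class = "community_spec")
}

# draw haplotypes respecting the pairwise distance floor; bounded retries
draw_haplotypes <- function(n, length, min_dist, max_tries = 200L) {
  haps <- character(0)
  tries <- 0L
  while (length(haps) < n) {
    cand <- random_seq(1L, length)
    if (all(vapply(haps, function(h) hamming(h, cand) >= min_dist, logical(1)))) {
      haps <- c(haps, cand)
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not satisfy min_pairwise_distance after ", max_tries,
             " retries; relax the constraint or shorten the distance floor")
      }
    }
  }
  haps
}

# apply substitution errors and draw Phred scores: erroneous bases get low
# quality (3-15), correct bases high (30-40), so the Q20 filter is
# exercisable
apply_errors <- function(seq, error_rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  err <- which(stats::runif(n) < error_rate)
  for (i in err) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  qual <- sample(30:40, n, replace = TRUE)
  if (length(err)) qual[err] <- sample(3:15, length(err), replace = TRUE)
  list(seq = paste(ch, collapse = ""), qual = qual, n_errors = length(err))
}

#' Simulate a mock-community paired-read library
#'
#' Builds each read pair from the 2-step-PCR layout: the forward read is
#' `tag + forward primer site + insert prefix`, the reverse read starts
#' with the reverse primer site followed by the reverse-complemented insert
#' suffix, both truncated to the read length. Substitution errors are
#' applied at the per-base rate with Phred scores consistent with the error
#' draw. The truth table maps every read to its haplotype and sample.
#'
#' @param spec A [community_spec()].
#' @param dir Optional directory; when given, `fwd.fastq`, `rev.fastq`,
#'   `truth.tsv` and `haplotypes.fasta` are written there.
#' @return A list with `pairs` (a `read_pairs`), `truth` (data.frame
#'   `read`, `sample`, `haplotype`, `contaminant`, `n_errors`,
#'   `tag_intact`), `haplotypes` (data.frame `haplotype`, `seq`,
#'   `proportion`), and `files` (paths, when `dir` was given).
#' @export
generate_community <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  manifest <- validate_manifest(spec$tags)
  primers <- validate_primers(spec$primers)

  hap_seq <- draw_haplotypes(spec$n_haplotypes, spec$haplotype_length,
                             spec$min_pairwise_distance)
  hap_id <- sprintf("hap%02d", seq_len(spec$n_haplotypes))
  fwd_site <- vapply(seq_len(spec$n_haplotypes),
                     function(i) realize_primer(primers$fwd), character(1))
  rev_site <- vapply(seq_len(spec$n_haplotypes),
                     function(i) realize_primer(primers$rev), character(1))
  template <- paste0(fwd_site, hap_seq, revcomp(rev_site))
  # single-deletion length variants used for the contaminant fraction
  del_pos <- sample.int(spec$haplotype_length, spec$n_haplotypes, replace = TRUE)
  variant_insert <- vapply(seq_len(spec$n_haplotypes), function(i) {
    paste0(substr(hap_seq[i], 1L, del_pos[i] - 1L),
           substr(hap_seq[i], del_pos[i] + 1L, spec$haplotype_length))
  }, character(1))
  template_var <- paste0(fwd_site, variant_insert, revcomp(rev_site))

  w <- stats::rlnorm(spec$n_haplotypes, spec$abundance_meanlog,
                     spec$abundance_sdlog)
  prop <- w / sum(w)

  n <- spec$n_read_pairs
  hap_of <- sample.int(spec$n_haplotypes, n, replace = TRUE, prob = prop)
  sample_of <- sample.int(nrow(manifest), n, replace = TRUE)
  contaminant <- stats::runif(n) < spec$length_variant_frac

  fwd <- vector("list", n)
  rev <- vector("list", n)
  n_errors <- integer(n)
  tag_intact <- logical(n)
  for (i in seq_len(n)) {
    tmpl <- if (contaminant[i]) template_var[hap_of[i]] else template[hap_of[i]]
    tag <- manifest$tag[sample_of[i]]
    f_raw <- substr(paste0(tag, tmpl), 1L, spec$read_length)
    r_raw <- substr(revcomp(tmpl), 1L, spec$read_length)
    f <- apply_errors(f_raw, spec$per_base_error_rate)
    r <- apply_errors(r_raw, spec$per_base_error_rate)
    fwd[[i]] <- f
    rev[[i]] <- r
    n_errors[i] <- f$n_errors + r$n_errors
    tag_intact[i] <- substr(f$seq, 1L, 8L) == tag
  }
  ids <- sprintf("read%06d", seq_len(n))
  fwd_df <- data.frame(
    id = paste0(ids, "/1"),
    seq = vapply(fwd, `[[`, character(1), "seq"),
    qual = phred_encode(lapply(fwd, `[[`, "qual")),
    stringsAsFactors = FALSE
  )
  rev_df <- data.frame(
    id = paste0(ids, "/2"),
    seq = vapply(rev, `[[`, character(1), "seq"),
    qual = phred_encode(lapply(rev, `[[`, "qual")),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    read = ids, sample = manifest$sample_id[sample_of],
    haplotype = hap_id[hap_of], contaminant = contaminant,
    n_errors = n_errors, tag_intact = tag_intact,
    stringsAsFactors = FALSE
  )
  out <- list(
    pairs = read_pairs(fwd_df, rev_df),
    truth = truth,
    haplotypes = data.frame(haplotype = hap_id, seq = hap_seq,
                            proportion = prop, stringsAsFactors = FALSE),
    spec = spec
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(fwd = file.path(dir, "fwd.fastq"),
                  rev = file.path(dir, "rev.fastq"),
                  truth = file.path(dir, "truth.tsv"),
                  haplotypes = file.path(dir, "haplotypes.fasta"))
    write_fastq(fwd_df, files$fwd)
    write_fastq(rev_df, files$rev)
    utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_fasta(data.frame(id = hap_id, seq = hap_seq,
                           count = rep(1L, length(hap_id))),
                files$haplotypes)
    out$files <- files
  }
  out
}

#' Specification of a simulated Yule-over-coalescent tree
#'
#' A species tree is generated by a pure-birth (Yule) process; within each
#' species, a fixed number of tips coalesce under a Kingman coalescent
#' whose rate is scaled so the expected within-species depth is the species
#' tree height divided by `depth_ratio`. Large ratios give the clean
#' barcode-gap structure GMYC assumes.
#'
#' @param n_species Number of species (>= 1; with 1, the tree is a single
#'   coalescent tree).
#' @param tips_per_species Tips sampled per species (default 6).
#' @param speciation_rate Yule birth rate (default 1).
#' @param depth_ratio Species-tree height over expected within-species
#'   coalescent depth (default 50).
#' @param seed Integer seed; mandatory.
#' @return A list of class `tree_spec`.
#' @export
tree_spec <- function(n_species = 5L, tips_per_species = 6L,
                      speciation_rate = 1, depth_ratio = 50, seed) {
  stopifnot(n_species >= 1, tips_per_species >= 1, speciation_rate > 0,
            depth_ratio > 0)
  if (missing(seed)) stop("tree_spec requires a seed")
  structure(as.list(environment()), class = "tree_spec")
}

# simulate a Kingman coalescent over k labelled tips; pairwise rate `rate`.
# When max_depth is finite the event heights are redrawn up to 50 times and
# finally rescaled into 0.9 * max_depth, so grafting into a pendant branch
# always succeeds. Returns list(newick = subtree without root branch, depth).
sim_coalescent <- function(labels, rate, max_depth = Inf) {
  k <- length(labels)
  if (k == 1L) return(list(newick = labels, depth = 0))
  j <- k:2
  for (try in 1:50) {
    ev <- cumsum(stats::rexp(k - 1L, rate * j * (j - 1) / 2))
    if (ev[k - 1L] < max_depth) break
  }
  if (ev[k - 1L] >= max_depth) ev <- ev * (0.9 * max_depth / ev[k - 1L])
  frag <- labels
  height <- rep(0, k)
  for (e in seq_len(k - 1L)) {
    t <- ev[e]
    pick <- sort(sample.int(length(frag), 2L))
    merged <- sprintf("(%s:%.15g,%s:%.15g)",
                      frag[pick[1L]], t - height[pick[1L]],
                      frag[pick[2L]], t - height[pick[2L]])
    frag <- c(frag[-pick], merged)
    height <- c(height[-pick], t)
  }
  list(newick = frag, depth = ev[k - 1L])
}

#' Simulate an ultrametric tree with known species membership
#'
#' @param spec A [tree_spec()].
#' @return A list with `newick` (text), `tree` (parsed `phylo`),
#'   `membership` (data.frame `tip`, `species`), `spec`, and `rates` (the
#'   generative speciation rate and coalescent pair rate, for recovery
#'   checks). The tree is ultrametric by construction.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  set.seed(spec$seed)
  k <- spec$tips_per_species
  labels_of <- function(i) sprintf("sp%d_t%d", i, seq_len(k))

  if (spec$n_species == 1L) {
    # a single within-species coalescent; rate chosen for unit expected depth
    rate <- 2 * (1 - 1 / k)
    nw <- paste0(sim_coalescent(labels_of(1L), rate)$newick, ";")
  } else {
    sp_tree <- ape::rphylo(spec$n_species, birth = spec$speciation_rate,
                           death = 0)
    th <- tree_heights(sp_tree)
    pendant <- numeric(spec$n_species)
    pendant[sp_tree$edge[, 2L][sp_tree$edge[, 2L] <= spec$n_species]] <-
      sp_tree$edge.length[sp_tree$edge[, 2L] <= spec$n_species]
    # scale to the *shallowest* species divergence so the ratio bounds the
    # barcode gap for every species pair, not just the deepest
    sp_internal <- th$height[(spec$n_species + 1L):(spec$n_species + sp_tree$Nnode)]
    target_depth <- min(sp_internal) / spec$depth_ratio
    rate <- 2 * (1 - 1 / max(k, 2L)) / target_depth
    subs <- lapply(seq_len(spec$n_species), function(i) {
      sim_coalescent(labels_of(i), rate, max_depth = 0.95 * pendant[i])
    })
    # recursive writer over the species-tree topology, grafting subtrees
    children <- split(sp_tree$edge[, 2L], sp_tree$edge[, 1L])
    elen <- numeric(spec$n_species + sp_tree$Nnode)
    elen[sp_tree$edge[, 2L]] <- sp_tree$edge.length
    write_nw <- function(v) {
      if (v <= spec$n_species) {
        sprintf("%s:%.15g", subs[[v]]$newick, pendant[v] - subs[[v]]$depth)
      } else {
        inner <- paste(vapply(children[[as.character(v)]], write_nw,
                              character(1)), collapse = ",")
        if (v == th$root) sprintf("(%s)", inner)
        else sprintf("(%s):%.15g", inner, elen[v])
      }
    }
    nw <- paste0(write_nw(th$root), ";")
  }
  tree <- parse_newick(nw)
  membership <- data.frame(
    tip = tree$tip.label,
    species = sub("_t\\d+$", "", tree$tip.label),
    stringsAsFactors = FALSE
  )
  list(newick = nw, tree = tree, membership = membership, spec = spec,
       rates = list(speciation = spec$speciation_rate,
                    coalescent_pair = rate))
}
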