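# Single-threshold GMYC species delimitation on ultrametric trees.
#
# The model places a time threshold T on an ultrametric tree: branching
# events older than T belong to a Yule-type diversification process with
# rate lambda_div * k^p_div (k = between-species lineages), events younger
# than T to within-species coalescent processes with combined rate
# lambda_coal * sum_j (m_j (m_j - 1))^p_coal over the within-species
# clusters j. The exponents generalise the linear dependence of the pure
# Yule / Kingman rates on lineage counts. Waiting times between events are
# exponential in the total rate; each event contributes the log rate of the
# component that produced it.

#' Parse a Newick tree
#'
#' @param x Newick text, or the path of a file containing one tree.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(x) {
  tr <- tryCatch(suppressWarnings(
    if (length(x) == 1L && file.exists(x)) {
      ape::read.tree(file = x)
    } else {
      ape::read.tree(text = x)
    }), error = function(e) NULL)
  if (is.null(tr)) stop("unparseable Newick input")
  if (is.null(tr$edge.length)) stop("Newick tree has no branch lengths")
  tr
}

# node heights (time before present): list(height = numeric over all node
# ids, H = root height, parent = parent id per node, n_tip)
tree_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  H <- max(depth[seq_len(n_tip)])
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  list(height = H - depth, H = H, parent = parent, n_tip = n_tip,
       root = n_tip + 1L)
}

#' Validate that a tree is ultrametric
#'
#' Flags every tip whose root-to-tip path length deviates by more than
#' `tol` (relative to tree height) from the reference depth. The reference
#' is the median root-to-tip distance, so on a clock-like tree with a few
#' aberrant tips it is the aberrant tips that get reported, not the
#' conforming majority.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param tol Relative tolerance (default 1e-6).
#' @return A list with `ok` (logical) and `violations` (data.frame `tip`,
#'   `deviation` in absolute time units; empty when ok).
#' @export
validate_ultrametric <- function(tree, tol = 1e-6) {
  th <- tree_heights(tree)
  depth <- th$H - th$height[seq_len(th$n_tip)]
  dev <- abs(depth - stats::median(depth))
  bad <- dev > tol * th$H
  list(ok = !any(bad),
       violations = data.frame(tip = tree$tip.label[bad],
                               deviation = dev[bad],
                               stringsAsFactors = FALSE))
}

assert_ultrametric <- function(tree, tol = 1e-6) {
  v <- validate_ultrametric(tree, tol)
  if (!v$ok) {
    stop("tree is not ultrametric within tolerance; worst tip '",
         v$violations$tip[which.max(v$violations$deviation)], "' deviates by ",
         format(max(v$violations$deviation)), call. = FALSE)
  }
  invisible(tree)
}

#' Branching times of an ultrametric tree
#'
#' Heights (time before present) of the internal nodes, sorted in
#' descending order; the first value is the root height.
#'
#' @param tree An ultrametric `phylo` object.
#' @return Numeric vector of length `n_tips - 1`.
#' @export
branching_times <- function(tree) {
  th <- tree_heights(tree)
  sort(th$height[(th$n_tip + 1L):(th$n_tip + tree$Nnode)], decreasing = TRUE)
}

# entity structure at threshold T: for every node at height <= T, climb to
# the highest ancestor still at height <= T; that ancestor is the entity
# root. Tips sit at height 0 by ultrametricity, so every tip has an entity.
entity_structure <- function(tree, threshold, th = tree_heights(tree)) {
  climb <- function(v) {
    while (v != th$root && th$height[th$parent[v]] <= threshold) v <- th$parent[v]
    v
  }
  tip_root <- vapply(seq_len(th$n_tip), climb, integer(1))
  ent_roots <- unique(tip_root)
  ent_of_tip <- match(tip_root, ent_roots)
  sizes <- tabulate(ent_of_tip, length(ent_roots))
  internal <- (th$n_tip + 1L):(th$n_tip + tree$Nnode)
  coal_nodes <- internal[th$height[internal] <= threshold]
  ev_heights <- lapply(seq_along(ent_roots), function(i) numeric(0))
  for (v in coal_nodes) {
    e <- match(climb(v), ent_roots)
    ev_heights[[e]] <- c(ev_heights[[e]], th$height[v])
  }
  list(ent_of_tip = ent_of_tip, sizes = sizes,
       ev_heights = lapply(ev_heights, sort))
}

#' Delimit GMYC entities at a threshold
#'
#' Cuts every branch crossing height `threshold`; the tip set of each
#' resulting subtree is one entity. Entities with two or more tips are
#' clusters, single tips are singletons.
#'
#' @param tree An ultrametric `phylo` object.
#' @param threshold Height at which to cut, in `[0, root height]`.
#' @return Data frame with columns `tip`, `entity` (id of the form
#'   `GMYC_<k>`, numbered in tip order) and `type` (`"cluster"` or
#'   `"singleton"`).
#' @export
delimit <- function(tree, threshold) {
  th <- tree_heights(tree)
  if (threshold < 0 || threshold > th$H + 1e-12 * th$H) {
    stop("threshold must lie in [0, root height]")
  }
  es <- entity_structure(tree, min(threshold, th$H), th)
  data.frame(
    tip = tree$tip.label,
    entity = sprintf("GMYC_%d", es$ent_of_tip),
    type = ifelse(es$sizes[es$ent_of_tip] >= 2L, "cluster", "singleton"),
    stringsAsFactors = FALSE
  )
}

# Piecewise layout of the mixed likelihood at threshold T.
# Pieces partition (0, root height], split at branching times and at T;
# zero-length pieces from simultaneous branching collapse away (their
# events keep their log-rate terms). Returns:
#   x        piece widths (ascending in time before present)
#   L        total lineage count within each piece
#   above    is the piece older than T
#   k_div    between-species lineages per piece: every lineage above T;
#            below T, the species stems crossing T (they persist, so the
#            diversification process still accrues survival exposure there;
#            at T = root height no lineage is older than T and k_div = 0)
#   mm       per piece: m_j*(m_j-1) for within-species clusters with m_j >= 2
#   ev_piece piece index directly below each branching event
#   ev_div   is each event a diversification (older than T) event
gmyc_layout <- function(tree, threshold, th = tree_heights(tree)) {
  n <- th$n_tip
  s <- sort(th$height[(n + 1L):(n + tree$Nnode)])
  H <- s[length(s)]
  if (threshold < 0 || threshold > H + 1e-12 * H) {
    stop("threshold must lie in [0, root height]")
  }
  threshold <- min(threshold, H)
  breaks <- sort(unique(c(0, s, threshold)))
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1L]
  mid <- (lo + hi) / 2
  L <- n - findInterval(mid, s)
  above <- mid > threshold

  es <- entity_structure(tree, threshold, th)
  n_stems <- if (threshold < H) length(es$sizes) else 0L
  mm <- vector("list", length(mid))
  for (k in which(!above)) {
    live <- which(es$sizes >= 2L)
    m <- vapply(live, function(e) {
      es$sizes[e] - sum(es$ev_heights[[e]] < mid[k])
    }, numeric(1))
    mm[[k]] <- m[m >= 2] * (m[m >= 2] - 1)
  }
  for (k in which(above)) mm[[k]] <- numeric(0)

  ev_piece <- match(s, hi)
  list(x = hi - lo, L = L, above = above,
       k_div = ifelse(above, L, n_stems), mm = mm,
       ev_piece = ev_piece, ev_div = s > threshold, H = H, n = n)
}

#' Log-likelihood of the single-threshold GMYC model
#'
#' Between consecutive branching events with waiting time x, the total
#' event rate is `lambda_div * k^p_div + lambda_coal * sum_j (m_j (m_j -
#' 1))^p_coal`, where `k` counts between-species lineages and `m_j` the
#' lineages of within-species cluster `j`. Above the threshold every
#' lineage is a between-species lineage; below it, `k` is the number of
#' species stems crossing the threshold — species persist to the present,
#' so the diversification process keeps accruing waiting-time exposure
#' below the threshold even though all events there are coalescences (at a
#' root-height threshold no lineage is older than the threshold and the
#' term vanishes). The log-likelihood sums, over events, the log rate of
#' the component that produced the event, minus the integral of the total
#' rate over the tree's depth.
#'
#' @param tree An ultrametric `phylo` object.
#' @param threshold Threshold height in `[0, root height]`. At 0 every tip
#'   is its own species and the coalescent term vanishes; at the root
#'   height all branching is coalescent and the model collapses to the
#'   single-process null.
#' @param params List or named vector with `lambda_div`, `p_div`,
#'   `lambda_coal`, `p_coal` (lambdas > 0).
#' @return The log-likelihood (finite for valid input).
#' @export
gmyc_loglik <- function(tree, threshold, params) {
  p <- as.list(params)
  lam_d <- p$lambda_div
  lam_c <- p$lambda_coal
  if (is.null(lam_d) || is.null(lam_c) || lam_d <= 0 || lam_c <= 0) {
    stop("lambda_div and lambda_coal must be positive")
  }
  lay <- gmyc_layout(tree, threshold)
  S <- vapply(lay$mm, function(m) sum(m^p$p_coal), numeric(1))
  rate_div <- ifelse(lay$k_div > 0, lam_d * lay$k_div^p$p_div, 0)
  rate_coal <- lam_c * S
  exposure <- sum((rate_div + rate_coal) * lay$x)
  ev_rate <- ifelse(lay$ev_div,
                    lam_d * lay$k_div[lay$ev_piece]^p$p_div,
                    lam_c * S[lay$ev_piece])
  sum(log(ev_rate)) - exposure
}

# profile fit of one component: N events with per-event log unit rates
# (log of k^p or of sum mm^p at the event's piece) and exposure integral
# A(p); lambda profiles out as N / A(p). Returns the maximised contribution
# and the component parameters. unit_exposure(p) and unit_logev(p) are
# closures over the layout.
profile_component <- function(N, unit_exposure, unit_logev, p_fixed = NULL) {
  if (N == 0L) {
    return(list(value = 0, lambda = NA_real_, p = NA_real_))
  }
  obj <- function(p) {
    A <- unit_exposure(p)
    N * log(N / A) + unit_logev(p) - N
  }
  if (!is.null(p_fixed)) {
    p_hat <- p_fixed
  } else {
    grid <- seq(0, 2, by = 0.1)
    vals <- vapply(grid, obj, numeric(1))
    p0 <- grid[which.max(vals)]
    opt <- stats::optimize(obj, c(max(0, p0 - 0.15), min(2, p0 + 0.15)),
                           maximum = TRUE, tol = 1e-8)
    p_hat <- if (opt$objective >= max(vals)) opt$maximum else p0
  }
  list(value = obj(p_hat), lambda = N / unit_exposure(p_hat), p = p_hat)
}

# maximised log-likelihood at one threshold (lambdas profiled analytically,
# exponents by deterministic grid + 1-D refinement)
fit_at_threshold <- function(lay, p_div = NULL, p_coal = NULL) {
  div_ev <- which(lay$ev_div)
  coal_ev <- which(!lay$ev_div)
  kd <- which(lay$k_div > 0)
  div <- profile_component(
    length(div_ev),
    function(p) sum(lay$k_div[kd]^p * lay$x[kd]),
    function(p) p * sum(log(lay$k_div[lay$ev_piece[div_ev]])),
    p_div
  )
  coal <- profile_component(
    length(coal_ev),
    function(p) sum(vapply(seq_along(lay$mm),
                           function(k) sum(lay$mm[[k]]^p) * lay$x[k], numeric(1))),
    function(p) sum(vapply(lay$ev_piece[coal_ev],
                           function(k) log(sum(lay$mm[[k]]^p)), numeric(1))),
    p_coal
  )
  list(logL = div$value + coal$value,
       params = c(lambda_div = div$lambda, p_div = div$p,
                  lambda_coal = coal$lambda, p_coal = coal$p))
}

#' Fit the single-process null model
#'
#' The null treats the whole tree as one uniform branching process with
#' rate `lambda * (n_i (n_i - 1))^p` over the `n_i` lineages of each
#' inter-event interval; `lambda` is profiled analytically and `p` is
#' optimised on `[0, 2]`.
#'
#' @param tree An ultrametric `phylo` object.
#' @param p Optional fixed rate exponent; when `NULL` (default) it is
#'   estimated.
#' @return A list with `lambda`, `p` and `logL`.
#' @export
gmyc_null <- function(tree, p = NULL) {
  assert_ultrametric(tree)
  lay <- gmyc_layout(tree, tree_heights(tree)$H)
  fit <- fit_at_threshold(lay, p_coal = p)
  list(lambda = unname(fit$params["lambda_coal"]),
       p = unname(fit$params["p_coal"]), logL = fit$logL)
}

#' Fit the single-threshold GMYC model
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' branching times, plus one just below the shallowest branching (every tip
#' its own species) and one at the root height (a single species; this
#' candidate coincides with the null model, so the likelihood-ratio
#' statistic is never negative). At each candidate the rate parameters are
#' maximised; the best candidate gives the fitted threshold, and entities
#' are delimited there. The likelihood-ratio test against the null uses a
#' chi-square reference with `df` degrees of freedom (default 3: threshold
#' plus the extra rate class; published usage varies, hence configurable).
#'
#' @param tree An ultrametric `phylo` object with at least 3 tips.
#' @param df Degrees of freedom of the chi-square reference (default 3).
#' @param p_div,p_coal Optional fixed rate exponents; estimated on `[0, 2]`
#'   when `NULL`.
#' @param tol Ultrametricity tolerance passed to [validate_ultrametric()].
#' @return An object of class `gmyc` with components `threshold`,
#'   `logL_gmyc`, `logL_null`, `LR`, `p_value`, `df`, `params`,
#'   `null_params`, `entities` (as [delimit()]), `n_species`, `n_clusters`,
#'   `n_singletons`, and `profile` (per-candidate threshold, logL and
#'   species count).
#' @export
gmyc <- function(tree, df = 3, p_div = NULL, p_coal = NULL, tol = 1e-6) {
  if (length(tree$tip.label) < 3L) stop("GMYC fit requires at least 3 tips")
  assert_ultrametric(tree, tol)
  th <- tree_heights(tree)
  s <- sort(unique(th$height[(th$n_tip + 1L):(th$n_tip + tree$Nnode)]))
  cand <- c(s[1L] / 2,
            if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2,
            th$H)
  fits <- lapply(cand, function(T) fit_at_threshold(gmyc_layout(tree, T, th),
                                                    p_div, p_coal))
  logLs <- vapply(fits, `[[`, numeric(1), "logL")
  best <- which.max(logLs)
  threshold <- cand[best]
  ents <- delimit(tree, threshold)
  ent_sizes <- table(ents$entity)
  logL_null <- fits[[length(fits)]]$logL  # root-height candidate == null
  LR <- 2 * (logLs[best] - logL_null)
  profile <- data.frame(
    threshold = cand, logL = logLs,
    n_species = vapply(cand, function(T) {
      length(unique(delimit(tree, T)$entity))
    }, numeric(1))
  )
  structure(list(
    tree = tree, threshold = threshold,
    logL_gmyc = logLs[best], logL_null = logL_null,
    LR = LR, p_value = stats::pchisq(LR, df, lower.tail = FALSE), df = df,
    params = fits[[best]]$params,
    null_params = gmyc_null_params_from(fits[[length(fits)]]),
    entities = ents,
    n_species = length(ent_sizes),
    n_clusters = sum(ent_sizes >= 2L),
    n_singletons = sum(ent_sizes == 1L),
    profile = profile,
    call = match.call()
  ), class = "gmyc")
}

gmyc_null_params_from <- function(fit) {
  c(lambda = unname(fit$params["lambda_coal"]),
    p = unname(fit$params["p_coal"]))
}

#' @export
print.gmyc <- function(x, ...) {
  cat("Single-threshold GMYC fit\n")
  cat("  tips:          ", length(x$tree$tip.label), "\n", sep = "")
  cat("  threshold:     ", format(x$threshold, digits = 6),
      " (time before present)\n", sep = "")
  cat("  GMYC species:  ", x$n_species, " (", x$n_clusters, " clusters, ",
      x$n_singletons, " singletons)\n", sep = "")
  cat("  logL:          ", format(x$logL_gmyc, digits = 8),
      "  (null ", format(x$logL_null, digits = 8), ")\n", sep = "")
  cat("  LR = ", format(x$LR, digits = 5), ", p = ",
      format.pval(x$p_value, digits = 4), " (chi-square, df = ", x$df, ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.gmyc <- function(object, ...) {
  print(object)
  cat("\nRate parameters (mixed model):\n")
  print(object$params)
  cat("\nNull (single-process) parameters:\n")
  print(object$null_params)
  sizes <- sort(table(object$entities$entity), decreasing = TRUE)
  cat("\nEntity sizes: ", paste(as.integer(sizes), collapse = " "), "\n")
  invisible(object)
}

#' @export
logLik.gmyc <- function(object, ...) {
  val <- object$logL_gmyc
  attr(val, "df") <- 5L  # two rates, two exponents, one threshold
  class(val) <- "logLik"
  val
}

#' @export
coef.gmyc <- function(object, ...) object$params

#' Plot a GMYC fit
#'
#' Draws the tree with the fitted threshold as a dashed vertical line and
#' tips coloured by delimited entity.
#'
#' @param x A `gmyc` object.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.gmyc <- function(x, ...) {
  th <- tree_heights(x$tree)
  ent <- match(x$entities$entity, unique(x$entities$entity))
  cols <- grDevices::hcl.colors(max(ent), "Dark 3")
  ape::plot.phylo(x$tree, tip.color = cols[ent], ...)
  graphics::abline(v = th$H - x$threshold, lty = 2, col = "grey30")
  graphics::mtext(sprintf("threshold = %.4g; %d GMYC species",
                          x$threshold, x$n_species), side = 3, cex = 0.8)
  invisible(x)
}

#' Build a demonstration ultrametric tree by UPGMA on Hamming distances
#'
#' Utility for demos and tests only: average-linkage clustering of
#' equal-length sequences gives a clock-like (ultrametric) dendrogram. This
#' is *not* a phylogenetic inference method and is no substitute for a
#' proper clock-model tree.
#'
#' @param seqs Named character vector of equal-length sequences (names
#'   become tip labels).
#' @return An ultrametric `phylo` object.
#' @export
hamming_upgma <- function(seqs) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  mat <- seq_char_matrix(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}
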