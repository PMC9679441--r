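test_that("Newick parsing and ultrametricity validation behave as specified", {
  tr <- parse_newick("((a:1,b:1):1,c:2);")
  v <- validate_ultrametric(tr)
  expect_true(v$ok)
  expect_equal(max(branching_times(tr)), 2)

  bad <- parse_newick("((a:1,b:2):1,c:2);")
  vb <- validate_ultrametric(bad)
  expect_false(vb$ok)
  expect_true("b" %in% vb$violations$tip)
  expect_error(gmyc(bad), "not ultrametric")
  expect_error(parse_newick("not a tree ("), "unparseable|parenthe")

  # simulator-emitted trees validate at a tight tolerance
  for (s in 1:5) {
    expect_true(validate_ultrametric(generate_tree(tree_spec(seed = s))$tree,
                                     tol = 1e-9)$ok)
  }
})

test_that("branching times are the internal node heights, descending", {
  expect_equal(branching_times(parse_newick("(a:3,b:3);")), 3)
  expect_equal(branching_times(parse_newick("((a:1,b:1):1,c:2);")), c(2, 1))
  # independent traversal oracle on a simulated tree
  sim <- generate_tree(tree_spec(seed = 23))
  tr <- sim$tree
  depths <- ape::node.depth.edgelength(tr)
  H <- max(depths)
  want <- sort(H - depths[(length(tr$tip.label) + 1):length(depths)],
               decreasing = TRUE)
  expect_equal(branching_times(tr), want)
  expect_equal(length(branching_times(tr)), length(tr$tip.label) - 1L)
})

test_that("the mixed log-likelihood matches a hand-computed interval sum", {
  # heights: (a,b) at 1, (c,d) at 0.5, ((c,d),e) at 3, root at 4; T = 2
  tr <- parse_newick("((a:1,b:1):3,((c:0.5,d:0.5):2.5,e:3):1);")
  ld <- 0.8; pd <- 1.3; lc <- 5; pc <- 0.7
  # entities at T=2: {a,b}, {c,d}, {e}; their 3 stems cross the threshold,
  # so the diversification process carries rate ld*3^pd throughout (0, 2].
  # ascending intervals: (0,.5] clusters {a,b}=2,{c,d}=2 ending in a
  # coalescence; (.5,1] cluster {a,b}=2 ending in a coalescence; (1,2]
  # coalescent-idle; (2,3] k=3 ending in a speciation; (3,4] k=2 ending at
  # the root
  manual <- (log(lc * 2 * 2^pc) - (lc * 2 * 2^pc + ld * 3^pd) * 0.5) +
            (log(lc * 2^pc) - (lc * 2^pc + ld * 3^pd) * 0.5) +
            (-ld * 3^pd * 1) +
            (log(ld * 3^pd) - ld * 3^pd * 1) +
            (log(ld * 2^pd) - ld * 2^pd * 1)
  got <- gmyc_loglik(tr, 2, list(lambda_div = ld, p_div = pd,
                                 lambda_coal = lc, p_coal = pc))
  expect_equal(got, manual, tolerance = 1e-12)

  expect_error(gmyc_loglik(tr, 5, list(lambda_div = 1, p_div = 1,
                                       lambda_coal = 1, p_coal = 1)),
               "threshold")
  expect_error(gmyc_loglik(tr, 1, list(lambda_div = -1, p_div = 1,
                                       lambda_coal = 1, p_coal = 1)),
               "positive")
})

test_that("the likelihood collapses to the pure single-process forms at the edges", {
  for (s in c(2, 14)) {
    tr <- generate_tree(tree_spec(seed = s))$tree
    par <- list(lambda_div = 1.7, p_div = 0.9, lambda_coal = 40, p_coal = 1.1)
    H <- max(branching_times(tr))
    # T = 0: every tip a species, coalescent term vanishes
    expect_equal(gmyc_loglik(tr, 0, par),
                 direct_single_process(tr, par$lambda_div, par$p_div,
                                       coalescent = FALSE),
                 tolerance = 1e-9)
    # T at the root: one species, the single-process coalescent likelihood
    expect_equal(gmyc_loglik(tr, H, par),
                 direct_single_process(tr, par$lambda_coal, par$p_coal,
                                       coalescent = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("the null fit matches the one-interval closed form and is nested", {
  # 2 tips, one interval of length x at p = 1: lambda-hat = 1/(2x)
  x <- 1.7
  f <- gmyc_null(parse_newick(sprintf("(a:%g,b:%g);", x, x)), p = 1)
  expect_equal(f$lambda, 1 / (2 * x), tolerance = 1e-10)
  expect_equal(f$logL, log(1 / x) - 1, tolerance = 1e-10)

  # nesting: the threshold fit is never worse than the null
  for (s in c(4, 9, 27)) {
    tr <- generate_tree(tree_spec(seed = s))$tree
    fit <- gmyc(tr)
    expect_gte(fit$logL_gmyc, fit$logL_null)
    expect_gte(fit$LR, 0)
    # self-consistency: reported optimum equals an independent recomputation
    expect_equal(fit$logL_gmyc,
                 gmyc_loglik(tr, fit$threshold, fit$params),
                 tolerance = 1e-8)
  }
})

test_that("delimitation cuts the tree into the expected entities", {
  tr <- parse_newick("((a:1,b:1):1,c:2);")
  d15 <- delimit(tr, 1.5)
  expect_equal(norm_partition(entities_partition(d15, "entity")),
               c("a,b", "c"))
  expect_equal(sort(unique(d15$type[d15$tip %in% c("a", "b")])), "cluster")
  expect_equal(d15$type[d15$tip == "c"], "singleton")
  # T above all nodes: one entity; T below all nodes: all singletons
  expect_equal(length(unique(delimit(tr, 2)$entity)), 1L)
  expect_equal(length(unique(delimit(tr, 0)$entity)), 3L)
  # entities partition the tips, and counts are monotone in T
  sim <- generate_tree(tree_spec(seed = 31))
  ns <- vapply(seq(0, 1, length.out = 8) * max(branching_times(sim$tree)),
               function(T) length(unique(delimit(sim$tree, T)$entity)),
               numeric(1))
  expect_true(all(diff(ns) <= 0))
  d <- delimit(sim$tree, 0.01)
  expect_setequal(d$tip, sim$tree$tip.label)
  expect_equal(anyDuplicated(d$tip), 0L)
})

test_that("well-separated simulated species are recovered by the fit", {
  hits <- 0
  for (s in 101:110) {
    sim <- generate_tree(tree_spec(n_species = 5, tips_per_species = 6,
                                   depth_ratio = 50, seed = s))
    fit <- gmyc(sim$tree)
    if (identical(norm_partition(entities_partition(sim$membership, "species")),
                  norm_partition(entities_partition(fit$entities, "entity")))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("on Yule-only trees the fit keeps the tips apart or stays null", {
  # a homogeneous pure-birth tree has no threshold structure: the fit
  # should either retain nearly every tip as its own species (threshold
  # near the present) or collapse to the single-process fit without
  # claiming significance — a single coalescent with exponent ~0.5 mimics
  # the Yule rate curve, so the two families genuinely overlap
  ns <- integer(10)
  for (s in 1:10) {
    sim <- generate_tree(tree_spec(n_species = 40, tips_per_species = 1,
                                   seed = s))
    fit <- gmyc(sim$tree)
    ns[s] <- fit$n_species
    expect_true(fit$n_species >= 0.9 * 40 || fit$p_value > 0.05)
  }
  expect_gte(median(ns), 36)
})

test_that("the gmyc object behaves like a fitted model", {
  sim <- generate_tree(tree_spec(seed = 51))
  fit <- gmyc(sim$tree)
  expect_s3_class(fit, "gmyc")
  expect_named(coef(fit), c("lambda_div", "p_div", "lambda_coal", "p_coal"))
  expect_equal(as.numeric(logLik(fit)), fit$logL_gmyc)
  expect_output(print(fit), "GMYC species")
  expect_output(summary(fit), "Rate parameters")
  expect_error(gmyc(parse_newick("(a:1,b:1);")), "at least 3 tips")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("generative rates are recovered on 200-tip trees", {
  # 25 species x 8 tips; exponents held at their generative value 1, so
  # lambda_div estimates the Yule rate and lambda_coal half the pairwise
  # coalescent rate (the model rate is lambda * m(m-1), Kingman's is
  # r * m(m-1)/2)
  errs <- matrix(NA_real_, 7, 2)
  for (i in 1:7) {
    sim <- generate_tree(tree_spec(n_species = 25, tips_per_species = 8,
                                   speciation_rate = 1, depth_ratio = 50,
                                   seed = 300 + i))
    fit <- gmyc(sim$tree, p_div = 1, p_coal = 1)
    truth_lc <- sim$rates$coalescent_pair / 2
    errs[i, 1] <- abs(fit$params[["lambda_div"]] - 1)
    errs[i, 2] <- abs(fit$params[["lambda_coal"]] - truth_lc) / truth_lc
  }
  expect_lte(median(errs[, 1]), 0.25)
  expect_lte(median(errs[, 2]), 0.25)
})
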