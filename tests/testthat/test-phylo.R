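test_that("model construction satisfies its invariants", {
  for (ex in c("POISSON", "LG")) {
    m <- phylo_model(ex, rates = "gamma", gamma_classes = 4, alpha = 0.8)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    expect_equal(sum(m$class_weights), 1, tolerance = 1e-12)
    # normalized to 1 expected substitution per unit length
    expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-10)
    P <- transition_matrix(m, 0.37)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10)
    expect_equal(transition_matrix(m, 0), diag(20), tolerance = 1e-8)
    # detailed balance of the stationary process
    expect_equal(m$pi * P[, 1], P[1, ] * m$pi[1], tolerance = 1e-10)
  }
  f <- empirical_frequencies(c(a = "AAAR"))
  expect_equal(sum(f), 1)
  expect_gt(f[1], f[2])
  expect_error(phylo_model("LG", frequencies = "empirical"), "empirical_freqs")
})

test_that("two-leaf limiting cases of the site likelihood", {
  m <- phylo_model("LG")
  tr <- ape::read.tree(text = "(A:1e-9,B:1e-9);")
  aln <- c(A = "AR", B = "AR")
  ll <- site_loglik(tr, aln, m)
  # at zero distance each site is a single equilibrium draw
  expect_equal(ll$site_loglik, log(m$pi[1:2]), tolerance = 1e-6,
               ignore_attr = TRUE)
  # gaps are missing data: an all-gap column contributes zero
  ll_gap <- site_loglik(tr, c(A = "A-", B = "A-"), m)
  expect_equal(ll_gap$site_loglik[2], 0, tolerance = 1e-9)

  expect_error(site_loglik(tr, c(A = "AR", C = "AR"), m), "mismatch")
})

test_that("pruning equals exhaustive state summation on quartets", {
  set.seed(141)
  for (i in 1:150) {
    qt <- random_quartet(n_sites = 10, gap_prob = if (i %% 3 == 0) 0.15 else 0)
    model <- if (i %% 2 == 0) phylo_model("LG") else phylo_model("POISSON")
    mine <- site_loglik(qt$tree, qt$alignment, model)$site_loglik
    oracle <- quartet_loglik_oracle(qt$lens, qt$states, model)
    expect_equal(mine, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("total log-likelihood is invariant to rerooting", {
  set.seed(142)
  m <- phylo_model("LG", rates = "gamma", gamma_classes = 4, alpha = 0.6)
  tr <- ape::rtree(6)
  aln <- setNames(vapply(1:6, function(i) random_protein(40), ""),
                  tr$tip.label)
  base <- site_loglik(ape::unroot(tr), aln, m)$total
  for (og in tr$tip.label[1:3]) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(site_loglik(rr, aln, m)$total, base, tolerance = 1e-8)
  }
})

test_that("branch-length optimization reaches the closed-form ML distance", {
  set.seed(143)
  m <- phylo_model("POISSON")
  a <- random_protein(300)
  bchars <- strsplit(a, "")[[1]]
  flip <- sample(300, 60)
  for (i in flip) bchars[i] <- sample(setdiff(AA20, bchars[i]), 1)
  aln <- c(A = a, B = paste(bchars, collapse = ""))
  p_hat <- 0.2
  d_closed <- -(19 / 20) * log(1 - (20 / 19) * p_hat)
  tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
  # the two-taxon split of the path length is not identifiable, so the
  # coordinate ascent may keep trading length between the edges: only the
  # fitted sum matters here
  fit <- suppressWarnings(optimize_branch_lengths(tr, aln, m, tol = 1e-7))
  expect_equal(sum(fit$tree$edge.length), d_closed, tolerance = 1e-5)
  # dist_ml agrees with the closed form too
  expect_equal(as.numeric(dist_ml(aln, m)), d_closed, tolerance = 1e-9)

  # identical sequences: distance collapses to zero
  aln0 <- c(A = a, B = a)
  fit0 <- suppressWarnings(optimize_branch_lengths(tr, aln0, m, tol = 1e-7))
  expect_lt(sum(fit0$tree$edge.length), 1e-5)

  # the trace never decreases
  set.seed(144)
  tr4 <- ape::rtree(4)
  aln4 <- setNames(vapply(1:4, function(i) random_protein(30), ""),
                   tr4$tip.label)
  before <- site_loglik(tr4, aln4, m)$total
  fit4 <- optimize_branch_lengths(tr4, aln4, m, tol = 1e-4)
  expect_gte(fit4$loglik, before)
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(145)
  tr <- ape::rtree(5)
  aln <- setNames(vapply(1:5, function(i) random_protein(60), ""),
                  tr$tip.label)
  pd <- phangorn::phyDat(do.call(rbind, strsplit(aln, "")), type = "AA")
  for (spec in list(list(m = phylo_model("POISSON"), model = NULL, k = 1),
                    list(m = phylo_model("LG"), model = "LG", k = 1))) {
    mine <- site_loglik(tr, aln, spec$m)$total
    ref <- phangorn::pml(tr, pd, model = spec$model)$logLik
    expect_equal(mine, ref, tolerance = 1e-8)
  }
  mg <- phylo_model("LG", rates = "gamma", gamma_classes = 4, alpha = 0.7)
  ref_g <- phangorn::pml(tr, pd, model = "LG", k = 4, shape = 0.7)$logLik
  expect_equal(site_loglik(tr, aln, mg)$total, ref_g, tolerance = 1e-8)
})

test_that("NNI search recovers a strong quartet from any start", {
  set.seed(146)
  m <- phylo_model("POISSON")
  true_tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.8,(C:0.1,D:0.1):0.8);")
  hist <- NULL
  # simulate data on the true tree directly via the package model
  sim_aln <- local({
    tr <- true_tree
    n_sites <- 120
    aa <- AA20
    root_states <- sample.int(20, n_sites, TRUE)
    seqs <- list()
    evolve <- function(states, len) {
      P <- transition_matrix(m, len)
      vapply(states, function(s) sample.int(20, 1, prob = P[s, ]),
             integer(1))
    }
    nodeL <- evolve(root_states, 0.8)
    nodeR <- evolve(root_states, 0.8)
    out <- list(A = evolve(nodeL, 0.1), B = evolve(nodeL, 0.1),
                C = evolve(nodeR, 0.1), D = evolve(nodeR, 0.1))
    vapply(out, function(s) paste(aa[s], collapse = ""), "")
  })
  starts <- list(
    ape::read.tree(text = "((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2);"),
    ape::read.tree(text = "((A:0.2,C:0.2):0.2,(B:0.2,D:0.2):0.2);"),
    ape::read.tree(text = "((A:0.2,D:0.2):0.2,(B:0.2,C:0.2):0.2);"))
  # exhaustive oracle: the AB|CD topology has the best ML score
  scores <- vapply(starts, function(s)
    optimize_branch_lengths(ape::unroot(s), sim_aln, m,
                            tol = 1e-4)$loglik, numeric(1))
  expect_equal(which.max(scores), 1L)
  for (st in starts) {
    res <- nni_search(st, sim_aln, m, tol = 1e-4)
    expect_identical(armroot:::.tree_splits(res$tree),
                     armroot:::.tree_splits(starts[[1]]))
    refit <- optimize_branch_lengths(res$tree, sim_aln, m, tol = 1e-6)
    expect_gte(refit$loglik, max(scores) - 1e-3)
  }
})

test_that("constrained NNI search honors constraint bipartitions", {
  set.seed(147)
  m <- phylo_model("POISSON")
  aln <- setNames(vapply(1:6, function(i) random_protein(60), ""),
                  paste0("t", 1:6))
  start <- nj_tree(aln, m)
  constraint <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  res <- nni_search(start, aln, m, constraint = constraint, tol = 1e-3,
                    max_iter = 5)
  expect_true(armroot:::.compatible_with_constraint(res$tree, constraint))
  bad <- ape::read.tree(text = "((t1,zz),(t3,t4));")
  expect_error(nni_search(start, aln, m, constraint = bad), "incompatible")
  # the NJ start never scores above the NNI result
  expect_gte(res$loglik,
             optimize_branch_lengths(ape::unroot(start), aln, m,
                                     tol = 1e-3)$loglik - 1e-6)
})

test_that("RELL machinery: symmetry, dominance, reproducibility", {
  set.seed(148)
  # identical site vectors: AU cannot distinguish the topologies
  v <- rnorm(200, -3)
  st_same <- cbind(T1 = v, T2 = v)
  au <- au_test(st_same, n_reps = 5000, seed = 10)
  expect_equal(unname(au$p_au["T1"]), 0.5, tolerance = 0.1)
  expect_equal(unname(au$p_au["T2"]), 0.5, tolerance = 0.1)

  # strict per-site dominance: the winner saturates, the loser dies
  st_dom <- cbind(T1 = v, T2 = v - 0.2)
  au_dom <- au_test(st_dom, n_reps = 1000, seed = 11)
  expect_gt(unname(au_dom$p_au["T1"]), 0.95)
  expect_lt(unname(au_dom$p_au["T2"]), 0.05)
  expect_true(au_dom$degenerate["T2"])
  kh_dom <- kh_test(st_dom, n_reps = 1000, seed = 11)
  expect_lt(unname(kh_dom["T2"]), 0.01)

  # bit-for-bit reproducibility under a fixed seed
  st <- null_site_table(150)
  expect_identical(au_test(st, n_reps = 500, seed = 3),
                   au_test(st, n_reps = 500, seed = 3))
  expect_identical(kh_test(st, n_reps = 500, seed = 3),
                   kh_test(st, n_reps = 500, seed = 3))

  tt <- topology_test(st, n_reps = 500, seed = 3)
  expect_equal(min(tt$deltaL), 0)
  expect_true(all(tt$p_KH >= 0 & tt$p_KH <= 1))
  expect_true(all(tt$p_AU >= 0 & tt$p_AU <= 1))
})

test_that("root split report: minimal hand-checkable cases", {
  good <- ape::read.tree(
    text = "((a__arm1:1,b__arm1:1):2,(a__arm2:1,b__arm2:1):2);")
  rep_good <- root_split_report(good)
  expect_true(rep_good$split_present)
  expect_true(ape::is.rooted(rep_good$rooted_tree))
  expect_true(ape::is.monophyletic(rep_good$rooted_tree,
                                   c("a__arm1", "b__arm1")))

  bad <- ape::read.tree(
    text = "((a__arm1:1,a__arm2:1):2,(b__arm1:1,b__arm2:1):2);")
  rep_bad <- root_split_report(bad)
  expect_false(rep_bad$split_present)
  expect_null(rep_bad$rooted_tree)

  expect_error(root_split_report(ape::rtree(4)), "arm")

  # group monophyly table
  groups <- c(a = "G1", b = "G1", c = "G2", d = "G2")
  tr <- ape::read.tree(text = paste0(
    "(((a__arm1:1,b__arm1:1):1,(c__arm1:1,d__arm1:1):1):2,",
    "((a__arm2:1,b__arm2:1):1,(c__arm2:1,d__arm2:1):1):2);"))
  rep2 <- root_split_report(tr, groups = groups)
  expect_true(all(rep2$group_monophyly$monophyletic))
})

test_that("root split RELL support is high for a planted duplication", {
  tr <- simulate_species_tree(4, 1, 0, seed = 151)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  hist <- duplication_history(arm_split_depth = 1.5)
  sim <- simulate_complex_sequences(tr, hist, phylo_model("POISSON"),
                                    seq_length = 150, seed = 152)
  sm <- build_arm_supermatrix(sim$alignments, default_paralog_map(),
                              species = tr$tip.label,
                              trim_keep_fraction = NULL, premerged = TRUE)
  nj <- nj_tree(sm$alignment, phylo_model("POISSON"))
  rep <- root_split_report(nj, alignment = sm$alignment,
                           model = phylo_model("POISSON"),
                           n_reps = 300, seed = 153)
  expect_true(rep$split_present)
  expect_gte(rep$support, 0.9)
})
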