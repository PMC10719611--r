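test_that("Jukes-Cantor distances follow the closed form and flag
           saturation", {
  same <- aln_from_sites(rep("AA", 20))
  expect_equal(jc_distance(same)$distance["a", "b"], 0)

  # 10% mismatches: d = -0.75 log(1 - 0.4/3)
  aln <- aln_from_sites(c(rep("AA", 90), rep("AC", 10)))
  expect_equal(jc_distance(aln)$distance["a", "b"],
               -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)

  # p >= 0.75 saturates at the ceiling
  sat <- aln_from_sites(c(rep("AC", 75), rep("AA", 25)))
  d <- jc_distance(sat)
  expect_true(d$saturated["a", "b"])
  expect_equal(d$distance["a", "b"], 5)

  # missing data: distances use shared sites only; zero overlap errors
  gap <- aln_from_sites(c("A-", "-C", "AA", "AA"))
  expect_equal(jc_distance(gap)$shared["a", "b"], 2)
  none <- aln_from_sites(c("A-", "-C"))
  expect_error(jc_distance(none), "no shared")
})

test_that("neighbor joining recovers additive topologies and solves the
           3-taxon system exactly", {
  # additive matrix from a known 4-taxon tree
  tru <- parse_newick("((a:0.1,b:0.2):0.15,(c:0.12,d:0.3):0.15);")
  D <- ape::cophenetic.phylo(tru)
  est <- neighbor_joining(D)
  expect_equal(rf_distance(est, tru), 0)
  expect_equal(sort(ape::cophenetic.phylo(est)[rownames(D), colnames(D)]),
               sort(D), tolerance = 1e-12)

  # 3 taxa: branch lengths solve the three-equation system
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  x <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(unname(x[c("a", "b", "c")]), c(1, 2, 3))

  # determinism on tied input
  tie <- matrix(1, 4, 4); diag(tie) <- 0
  dimnames(tie) <- list(letters[1:4], letters[1:4])
  expect_identical(ape::write.tree(suppressWarnings(neighbor_joining(tie))),
                   ape::write.tree(suppressWarnings(neighbor_joining(tie))))

  # consistency on random additive matrices up to 10 taxa
  set.seed(37)
  for (n in c(6, 8, 10)) {
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    est <- neighbor_joining(ape::cophenetic.phylo(tr))
    expect_equal(rf_distance(est, tr), 0)
  }
})

test_that("bootstrap support behaves at both signal extremes", {
  sp <- parse_newick("((a:0.05,b:0.05):0.4,(c:0.05,d:0.05):0.4);")
  aln <- sim_alignment(sp, 1000, gamma_shape = Inf, k_categories = 1,
                       seed = 19)

  # n_reps = 0: reference tree, no supports
  ref <- bootstrap_support(aln, n_reps = 0)
  expect_null(ref$node.label)

  # strong clean signal: the focal split gets >= 95%
  bt <- bootstrap_support(aln, n_reps = 100, seed = 19)
  key <- bipartitions(sp)
  freqs <- attr(bt, "split_freqs")
  expect_gte(freqs[[key]], 95)

  # signal-free alignment: the three resolutions of the quartet soak up
  # all replicates between them
  flat <- aln_from_sites(rep("AAAA", 30))
  bf <- suppressWarnings(bootstrap_support(flat, n_reps = 50, seed = 2))
  fr <- attr(bf, "split_freqs")
  expect_equal(sum(fr), 50)
})

test_that("quartet scores match the path-length oracle and the full
           agreement count", {
  set.seed(43)
  tr <- ape::unroot(ape::rtree(6))
  gts <- rep(list(tr), 10)
  expect_equal(quartet_score(tr, gts), 10 * choose(6, 4))

  # direct conflict on 4 taxa scores zero
  q1 <- parse_newick("((a,b),(c,d));")
  q2 <- parse_newick("((a,c),(b,d));")
  expect_equal(quartet_score(q2, list(q1)), 0)

  # oracle equivalence on random 7-leaf inputs (subset leaf sets allowed)
  for (rep in 1:3) {
    cand <- ape::unroot(ape::rtree(7))
    gts <- lapply(1:4, function(i) {
      gt <- ape::rtree(7, tip.label = cand$tip.label)
      k <- sample(0:2, 1)
      if (k > 0) gt <- ape::drop.tip(gt, sample(cand$tip.label, k))
      gt
    })
    expect_equal(quartet_score(cand, gts), quartet_score_oracle(cand, gts))
  }
})

test_that("the exact quartet species tree equals the exhaustive oracle and
           majority inputs win", {
  set.seed(47)
  tr <- ape::unroot(ape::rtree(6))
  expect_equal(rf_distance(exact_quartet_species_tree(rep(list(tr), 20)), tr), 0)

  # 60/40 mixture of NNI-adjacent topologies: majority wins
  t1 <- parse_newick("((a,b),((c,d),(e,f)));")
  t2 <- phangorn::rNNI(t1, 1)
  est <- exact_quartet_species_tree(c(rep(list(t1), 6), rep(list(t2), 4)))
  expect_equal(rf_distance(est, ape::unroot(t1)), 0)

  # returned score is the max over exhaustive enumeration, scored by the
  # independent path-length oracle
  gts <- lapply(1:5, function(i) ape::rtree(6, tip.label = letters[1:6]))
  est <- exact_quartet_species_tree(gts)
  all6 <- phangorn::allTrees(6, rooted = FALSE, tip.label = sort(letters[1:6]))
  oracle_best <- max(vapply(seq_along(all6), function(i)
    quartet_score_oracle(all6[[i]], gts), numeric(1)))
  expect_equal(attr(est, "quartet_score"), oracle_best)
  expect_equal(quartet_score_oracle(est, gts), oracle_best)

  expect_error(exact_quartet_species_tree(list(ape::rtree(12))), "greedy")
})

test_that("greedy search agrees with exact search at low discordance and
           is deterministic", {
  set.seed(53)
  for (rep in 1:5) {
    sp <- sim_yule_tree(7, 1, seed = 530 + rep)
    gts <- lapply(1:25, function(i)
      if (runif(1) < 0.2) phangorn::rNNI(sp, 1) else sp)
    g <- greedy_quartet_species_tree(gts)
    e <- exact_quartet_species_tree(gts)
    expect_equal(rf_distance(g, e), 0)
  }
  gts <- rep(list(sim_yule_tree(8, 1, seed = 59)), 5)
  expect_identical(ape::write.tree(greedy_quartet_species_tree(gts)),
                   ape::write.tree(greedy_quartet_species_tree(gts)))
})

test_that("the species-tree stage never scores below the truth and
           recovers it exactly without discordance", {
  # at 10 taxa, 60 loci, 500 sites, 10% discordance the quartet optimizer
  # must never return a tree scoring below the true species tree
  recovered <- 0L
  for (rep in 1:6) {
    sp <- sim_yule_tree(10, 1, seed = 5000 + rep)
    cfg <- sim_config(seed = 6000 + rep, n_taxa = 10, n_loci = 60,
                      sites_per_locus = 500, discordance_prob = 0.1)
    loci <- sim_locus_collection(sp, cfg)
    gts <- lapply(loci, function(l)
      suppressWarnings(neighbor_joining(jc_distance(l$alignment))))
    est <- greedy_quartet_species_tree(gts)
    expect_gte(quartet_score(est, gts), quartet_score(ape::unroot(sp), gts))
    recovered <- recovered + (rf_distance(est, ape::unroot(sp)) == 0)
  }
  expect_gte(recovered, 4L)

  # zero discordance: exact topology recovery
  sp <- sim_yule_tree(10, 1, seed = 7001)
  cfg <- sim_config(seed = 7101, n_taxa = 10, n_loci = 60,
                    sites_per_locus = 500, discordance_prob = 0)
  loci <- sim_locus_collection(sp, cfg)
  gts <- lapply(loci, function(l)
    suppressWarnings(neighbor_joining(jc_distance(l$alignment))))
  expect_equal(rf_distance(greedy_quartet_species_tree(gts),
                           ape::unroot(sp)), 0)
})
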