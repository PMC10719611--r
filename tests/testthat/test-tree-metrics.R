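test_that("bipartitions are canonical, non-trivial, and rooting-invariant", {
  expect_equal(bipartitions(parse_newick("((a,b),(c,d));")),
               bipartitions(parse_newick("(a,b,(c,d));")))
  expect_length(bipartitions(parse_newick("((a,b),(c,d));")), 1L)
  # 5-leaf caterpillar: two non-trivial splits
  cat5 <- parse_newick("((((a,b),c),d),e);")
  expect_length(bipartitions(cat5), 2L)
  # fewer than 4 leaves: empty set
  expect_length(bipartitions(parse_newick("((a,b),c);")), 0L)
})

test_that("RF distance matches examples, the phangorn oracle, and metric
           axioms", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, parse_newick("((a,b),(c,e));")), "leaf sets")

  set.seed(17)
  trees <- replicate(12, ape::rtree(8), simplify = FALSE)
  for (i in 1:11) {
    d <- rf_distance(trees[[i]], trees[[i + 1]])
    # independent oracle: phangorn's compiled RF
    expect_equal(d, as.numeric(phangorn::RF.dist(trees[[i]], trees[[i + 1]])))
    # symmetry and identity
    expect_equal(d, rf_distance(trees[[i + 1]], trees[[i]]))
    expect_equal(rf_distance(trees[[i]], trees[[i]]), 0)
  }
  # triangle inequality on sampled triples
  for (k in 1:8) {
    tri <- sample(trees, 3)
    expect_lte(rf_distance(tri[[1]], tri[[3]]),
               rf_distance(tri[[1]], tri[[2]]) + rf_distance(tri[[2]], tri[[3]]))
  }
  # normalized variant is in [0, 1]
  expect_lte(rf_distance(trees[[1]], trees[[2]], normalized = TRUE), 1)
})

test_that("classical MDS reconstructs Euclidean configurations", {
  # three points at equal pairwise distance: an equilateral triangle
  D <- matrix(2, 3, 3); diag(D) <- 0
  pts <- classical_mds(D)
  expect_equal(as.vector(dist(pts)), rep(2, 3), tolerance = 1e-9)

  # all-zero distances collapse to the origin
  expect_equal(max(abs(classical_mds(matrix(0, 4, 4)))), 0)

  # any Euclidean matrix is reconstructed to 1e-9 with k = N - 1
  set.seed(23)
  X <- matrix(rnorm(8 * 3), 8, 3)
  D8 <- as.matrix(dist(X))
  emb <- classical_mds(D8, k = 7)
  expect_lt(max(abs(as.matrix(dist(emb)) - D8)), 1e-9)

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # non-Euclidean input warns about truncated eigenvalues
  bad <- matrix(c(0, 1, 1, 1,
                  1, 0, 1, 1,
                  1, 1, 0, 3,
                  1, 1, 3, 0), 4, 4)
  expect_warning(classical_mds(bad, k = 3), "negative eigenvalues")
})

test_that("centroid distances are translation-invariant and symmetric", {
  D <- matrix(2, 3, 3); diag(D) <- 0
  pts <- classical_mds(D)
  cd <- centroid_distances(pts)
  expect_equal(max(cd) - min(cd), 0, tolerance = 1e-9) # equilateral
  expect_equal(unname(centroid_distances(matrix(c(5, 7), 1, 2))), 0)
  shifted <- sweep(pts, 2, c(100, -40), `+`)
  expect_equal(centroid_distances(shifted), cd, tolerance = 1e-9)
})

test_that("inclusion sets reproduce the 61..489 arithmetic and nest", {
  ids <- sprintf("L%03d", 1:489)
  sets <- make_inclusion_sets(ids)
  expect_equal(lengths(sets), c(61, 122, 183, 244, 305, 366, 427, 489))
  expect_identical(sets[[1]], ids[1:61])
  for (k in 1:7) expect_true(all(sets[[k]] %in% sets[[k + 1]]))

  expect_equal(lengths(make_inclusion_sets(letters[1:8])), 1:8)
  expect_error(make_inclusion_sets(letters[1:5]), "at least 8")
})

test_that("the sensitivity grid crosses 8 bin subsets with 8 inclusion
           sets and concatenates the right sites", {
  set.seed(29)
  sp <- sim_yule_tree(6, 1, seed = 29)
  loci <- list()
  for (i in 1:10) {
    a <- sim_alignment(sp, 150, gamma_shape = 0.4, seed = 300 + i)
    tab <- tiger_table(a)
    loci[[sprintf("L%02d", i)]] <- list(alignment = a, bins = tab$bin)
  }
  retained <- filter_loci_all_bins(lapply(loci, `[[`, "bins"))
  expect_gte(length(retained), 8L)
  ranking <- sort(retained)
  jobs <- build_sensitivity_sets(loci, ranking)
  expect_length(jobs, 64L)

  # maximal job holds every variant site of every retained locus
  maxjob <- jobs[["b8_s8"]]
  expect_setequal(maxjob$loci, retained)
  expect_equal(ncol(maxjob$alignment),
               sum(vapply(loci[retained],
                          function(l) sum(l$bins >= 2), 0L)))

  # concatenated length = sum of member locus lengths for that bin subset
  j25 <- jobs[["b2_s5"]]
  expect_equal(ncol(j25$alignment),
               sum(vapply(loci[j25$loci],
                          function(l) sum(l$bins >= 2 & l$bins <= 4), 0L)))

  # ending-bin labelling by default; bin-count on request
  expect_equal(jobs[["b2_s5"]]$label, "bins2-4_set5")
  jc <- build_sensitivity_sets(loci, ranking, label_style = "bin_count")
  expect_equal(jc[["b2_s5"]]$label, "nbins3_set5")
})

test_that("support grids record per-clade support and flag absent clades", {
  ref <- parse_newick("((a,b)100,(c,d)100,(e,f)100);")
  present <- parse_newick("((a,b)90,(c,d)80,(e,f)70);")
  conflicting <- parse_newick("((a,c)60,(b,d)55,(e,f)50);")
  grids <- support_grid(ref, list(present, conflicting),
                        bin_subset = c(1, 2), inclusion_set = c(1, 1))
  key_ab <- setdiff(bipartitions(ref), bipartitions(conflicting))
  # ab|... clade: present in job 1, absent in job 2
  ab <- grids[[intersect(key_ab, names(grids))[1]]]
  expect_false(is.na(ab[1, 1]))
  expect_true(is.na(ab[2, 1]))
  # shared clade ef: support read from both trees
  ef <- grids[[intersect(bipartitions(conflicting), names(grids))[1]]]
  expect_equal(sort(ef[!is.na(ef)]), c(50, 70))
  expect_error(
    support_grid(ref, list(parse_newick("((a,b),(c,x),(e,f));")), 1, 1),
    "leaf set")
})
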