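test_that("transition probabilities behave at the limits and conserve
           probability", {
  expect_equal(transition_probability(0.7, 0), diag(2),
               ignore_attr = TRUE)
  expect_equal(transition_probability(0.7, 1e9),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
  set.seed(61)
  for (i in 1:10) {
    P <- transition_probability(runif(1, 0.01, 5), runif(1, 0, 10))
    expect_equal(rowSums(P), c(tolerant = 1, susceptible = 1))
  }
  expect_error(transition_probability(0.5, -1), "negative")
  expect_error(transition_probability(-1, 1), "positive")
})

test_that("the pruning likelihood matches direct enumeration over root
           states", {
  tr <- parse_newick("(a:0.3,b:0.7);")
  traits <- c(a = "tolerant", b = "tolerant")
  r <- 0.8
  P1 <- transition_probability(r, 0.3)
  P2 <- transition_probability(r, 0.7)
  manual <- 0.5 * (P1[1, 1] * P2[1, 1] + P1[2, 1] * P2[2, 1])
  expect_equal(pruning_likelihood(tr, traits, r), log(manual))

  # mixed tips at vanishing rate: likelihood collapses
  mixed <- c(a = "tolerant", b = "susceptible")
  expect_lt(pruning_likelihood(tr, mixed, 1e-8),
            pruning_likelihood(tr, mixed, 0.5))
  expect_lt(pruning_likelihood(tr, mixed, 1e-8), -15)

  # invariant to node-order representation (ladderized or not)
  set.seed(67)
  tr6 <- ape::rtree(6)
  st <- random_traits(tr6)
  expect_equal(pruning_likelihood(ape::ladderize(tr6), st, 0.4),
               pruning_likelihood(tr6, st, 0.4))
  expect_error(pruning_likelihood(tr6, st[-1], 0.4), "leaf without state")
})

test_that("the rate MLE is a local optimum and hits the boundary for
           constant tips", {
  set.seed(71)
  tr <- sim_yule_tree(20, 1, seed = 71)
  st <- sim_binary_trait(tr, 0.4, 0.4, seed = 72)$tip_states
  r_hat <- as.numeric(mle_rate(tr, st))
  ll <- function(r) pruning_likelihood(tr, st, r)
  expect_gte(ll(r_hat) + 1e-8, ll(2 * r_hat))
  expect_gte(ll(r_hat) + 1e-8, ll(r_hat / 2))

  const <- setNames(rep("tolerant", ape::Ntip(tr)), tr$tip.label)
  expect_warning(rb <- mle_rate(tr, const), "lower bound")
  expect_equal(as.numeric(rb), 1e-6)
  expect_true(attr(rb, "boundary"))
})

test_that("marginal reconstruction equals brute-force enumeration and
           respects symmetry limits", {
  # symmetric 4-tip star: root posterior is (1/2, 1/2)
  star <- parse_newick("(a:1,b:1,c:1,d:1);")
  stx <- c(a = "tolerant", b = "tolerant",
           c = "susceptible", d = "susceptible")
  m <- marginal_asr(star, stx, 0.5)
  expect_equal(unname(m$probs[1, ]), c(0.5, 0.5))

  # both children tolerant on near-zero branches: parent certainty
  cherry <- parse_newick("((a:0.0001,b:0.0001):1,c:1);")
  mc <- marginal_asr(cherry, c(a = "tolerant", b = "tolerant",
                               c = "susceptible"), 0.5)
  anc <- as.character(ape::getMRCA(mc$tree, c("a", "b")))
  expect_gt(mc$probs[anc, "tolerant"], 0.99)

  # exhaustive oracle on random 6-leaf trees
  set.seed(73)
  for (rep in 1:3) {
    tr <- ape::rtree(6)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1.5)
    st <- random_traits(tr)
    r <- runif(1, 0.2, 1)
    m <- marginal_asr(tr, st, r)
    o <- marginal_oracle(tr, st, r)
    expect_equal(unname(m$probs), unname(o[rownames(m$probs), ]),
                 tolerance = 1e-10)
    expect_equal(unname(rowSums(m$probs)), rep(1, nrow(m$probs)))
  }
})

test_that("the MCMC reconstruction matches the exact marginal at a fixed
           rate and is reproducible", {
  set.seed(79)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
  st <- random_traits(tr)
  m <- marginal_asr(tr, st, 0.5)
  settings <- mcmc_settings(n_generations = 3e4, n_chains = 2,
                            sample_interval = 5, burn_in_samples = 200,
                            seed = 80)
  mc <- bbm_mcmc(tr, st, settings, fixed_rate = 0.5)
  # pooled frequencies within 3 Monte-Carlo standard errors of the exact
  # posterior (draws are independent at fixed rate)
  n_draws <- mc$n_samples_kept * 2
  se <- pmax(sqrt(m$probs * (1 - m$probs) / n_draws), 1e-3)
  expect_true(all(abs(mc$probs - m$probs) < 3.5 * se))

  mc2 <- bbm_mcmc(tr, st, settings, fixed_rate = 0.5)
  expect_identical(mc$probs, mc2$probs)

  expect_error(mcmc_settings(n_generations = 1000, sample_interval = 10,
                             burn_in_samples = 100), "burn_in")
})

test_that("independent MCMC chains agree on node posteriors", {
  tr <- sim_yule_tree(12, 1, seed = 83)
  st <- sim_binary_trait(tr, 0.3, 0.3, seed = 84)$tip_states
  fit <- bbm_mcmc(tr, st,
                  mcmc_settings(n_generations = 5e4, n_chains = 2,
                                sample_interval = 10,
                                burn_in_samples = 500, seed = 85))
  diffs <- abs(fit$chain_probs[[1]][, 1] - fit$chain_probs[[2]][, 1])
  expect_lt(mean(diffs), 0.05)
  expect_equal(unname(rowSums(fit$probs)), rep(1, nrow(fit$probs)))
  # rate posterior brackets a plausible value
  expect_true(fit$rate[["lo95"]] < fit$rate[["hi95"]])
})

test_that("pruning to scored taxa mirrors the published 48-to-35
           arithmetic and the suppression rule", {
  # no missing states: identity
  tr <- sim_yule_tree(6, 1, seed = 87)
  full <- setNames(rep(c("tolerant", "susceptible"), 3), tr$tip.label)
  expect_equal(rf_distance(prune_to_scored(tr, full), tr), 0)

  # removing one cherry member: the sibling inherits the summed length
  cherry <- parse_newick("((a:1,b:2):3,c:4);")
  pr <- prune_to_scored(cherry, c(a = "tolerant", c = "susceptible"))
  expect_equal(sort(pr$edge.length), c(4, 4)) # a: 1 + 3, c: 4

  # 48 species, 13 unscored: 35 tips survive
  traits48 <- species_tolerance(as_traits = TRUE)
  tr48 <- sim_yule_tree(48, 1, seed = 88)
  tr48$tip.label <- names(traits48)
  expect_equal(ape::Ntip(prune_to_scored(tr48, traits48)), 35L)
  expect_error(prune_to_scored(tr48, traits48[1]), "fewer than 2")
})

test_that("Sankoff loss counting equals exhaustive enumeration", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  st <- c(A = "tolerant", B = "susceptible",
          C = "tolerant", D = "susceptible")
  res <- count_losses(tr, st)
  expect_equal(res$transitions, 2L)
  expect_equal(res$losses, 2L)

  all_tol <- setNames(rep("tolerant", 4), LETTERS[1:4])
  res0 <- count_losses(tr, all_tol)
  expect_equal(res0$transitions, 0L)
  expect_equal(res0$losses, 0L)

  set.seed(89)
  for (n in c(5, 7, 8)) {
    tr <- ape::rtree(n, tip.label = paste0("s", 1:n))
    st <- random_traits(tr)
    for (root_state in TRAIT_STATES) {
      got <- count_losses(tr, st, root_state)
      want <- sankoff_oracle(tr, st, root_state)
      expect_equal(got$transitions, want$transitions)
      expect_equal(got$losses, want$losses)
      expect_lte(got$losses, got$transitions)
      # the witness labelling realises the reported counts
      s <- match(got$states, TRAIT_STATES)
      tt <- 0L; ll <- 0L
      po <- got$tree
      for (k in seq_len(nrow(po$edge))) {
        a <- s[po$edge[k, 1]]; b <- s[po$edge[k, 2]]
        if (a != b) { tt <- tt + 1L; if (a == 1 && b == 2) ll <- ll + 1L }
      }
      expect_equal(tt, got$transitions)
      expect_equal(ll, got$losses)
    }
  }
})
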