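## Seeded generators for every input the pipeline consumes: Yule species
## trees, locus alignments evolved under Jukes-Cantor with discrete-gamma
## rate heterogeneity (optionally on NNI-perturbed gene trees), binary
## trait histories under a two-state Markov chain, and vial-level
## binomial survival counts with a treatment effect on the logit scale.

#' Simulation configuration
#'
#' Bundles the generator parameters with validation. Defaults are the
#' desk-scale study conditions used throughout the package's property
#' checks: 12 taxa, 50 loci of 500 sites, moderate rate heterogeneity,
#' 10% gene-tree discordance, symmetric trait rates, and the assay design
#' of five replicate vials per arm at doses 0 and 50 ug/g with 20 larvae
#' per vial.
#'
#' @param seed RNG seed (all generators fully reproducible under it).
#' @param n_taxa,birth_rate Yule species-tree parameters.
#' @param n_loci,sites_per_locus locus collection dimensions.
#' @param gamma_shape,k_categories discrete-gamma among-site rate model.
#' @param discordance_prob probability a locus evolves on a one-NNI
#'   perturbation of the species tree.
#' @param r01,r10 trait gain (susceptible -> tolerant) and loss
#'   (tolerant -> susceptible) rates.
#' @param root_dist root state distribution over (tolerant, susceptible).
#' @param p0 control-arm survival probability.
#' @param beta toxin effect on the logit scale.
#' @param n_vials,larvae_per_vial,dose assay design.
#' @export
sim_config <- function(seed = 1L, n_taxa = 12L, birth_rate = 1,
                       n_loci = 50L, sites_per_locus = 500L,
                       gamma_shape = 0.5, k_categories = 4L,
                       discordance_prob = 0.1,
                       r01 = 0.3, r10 = 0.3, root_dist = c(0.5, 0.5),
                       p0 = 0.4, beta = -3, n_vials = 5L,
                       larvae_per_vial = 20L, dose = 50) {
  stopifnot(n_taxa >= 2L, birth_rate > 0, n_loci >= 1L,
            sites_per_locus >= 1L, gamma_shape > 0, k_categories >= 1L,
            discordance_prob >= 0, discordance_prob <= 1,
            r01 > 0, r10 > 0, length(root_dist) == 2L,
            all(root_dist >= 0), abs(sum(root_dist) - 1) < 1e-9,
            p0 > 0, p0 < 1, n_vials >= 1L, larvae_per_vial >= 1L, dose > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Forward simulation: with `k` extant lineages the waiting time to the
#' next split is exponential with rate `k * birth_rate` and a uniformly
#' chosen lineage splits. The process stops once `n_taxa` lineages exist,
#' plus one final waiting time, and the surviving lineages are cut there,
#' giving an ultrametric tree. Leaves are labelled `t1..tn` in order of
#' lineage creation.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed optional RNG seed.
#' @return rooted binary ultrametric `phylo`.
#' @export
sim_yule_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  stopifnot(birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  max_lin <- 2L * n_taxa - 1L
  parent <- rep(NA_integer_, max_lin)
  start <- numeric(max_lin)
  end <- rep(NA_real_, max_lin)
  active <- 1L # lineage ids; lineage 1 is the root stem (dropped later)
  n_lin <- 1L
  t_now <- 0
  while (length(active) < n_taxa) {
    k <- length(active)
    t_now <- t_now + rexp(1L, k * birth_rate)
    i <- if (k == 1L) 1L else sample.int(k, 1L)
    who <- active[i]
    end[who] <- t_now
    kids <- n_lin + 1:2
    parent[kids] <- who
    start[kids] <- t_now
    n_lin <- n_lin + 2L
    active <- c(active[-i], kids)
  }
  t_end <- t_now + rexp(1L, n_taxa * birth_rate)
  end[active] <- t_end
  ids <- seq_len(n_lin)
  is_tip <- ids %in% active
  splitters <- ids[!is_tip] # includes lineage 1 (root)
  node_of <- integer(n_lin)
  node_of[ids[is_tip]] <- seq_len(n_taxa) # tips numbered by creation order
  node_of[splitters] <- n_taxa + seq_along(splitters)
  has_parent <- ids[!is.na(parent)]
  edge <- cbind(node_of[parent[has_parent]], node_of[has_parent])
  tree <- list(edge = edge,
               edge.length = end[has_parent] - start[has_parent],
               tip.label = paste0("t", seq_len(n_taxa)),
               Nnode = n_taxa - 1L)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a locus alignment under Jukes-Cantor with discrete-gamma rates
#'
#' Each site draws one of `k_categories` discrete-gamma rate multipliers
#' (mean 1, shape `gamma_shape`; `Inf` means rate-homogeneous) and
#' evolves independently on the tree under the Jukes-Cantor model with
#' root states uniform over `{A,C,G,T}` (via [phangorn::simSeq()] per
#' rate category).
#'
#' @param tree `phylo` with branch lengths (expected substitutions/site).
#' @param n_sites number of sites (>= 1).
#' @param gamma_shape gamma shape parameter (> 0, or `Inf`).
#' @param k_categories number of discrete rate categories.
#' @param seed optional RNG seed.
#' @return alignment matrix with per-site rate categories in attribute
#'   `"rate_category"` and the category rates in `"category_rates"`.
#' @export
sim_alignment <- function(tree, n_sites, gamma_shape = 0.5,
                          k_categories = 4L, seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  stopifnot(n_sites >= 1L, gamma_shape > 0, k_categories >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rates <- if (is.infinite(gamma_shape) || k_categories == 1L)
    rep(1, k_categories)
  else phangorn::discrete.gamma(gamma_shape, k_categories)
  cat_of <- sample.int(k_categories, n_sites, replace = TRUE)
  aln <- matrix("A", ape::Ntip(tree), n_sites,
                dimnames = list(tree$tip.label, NULL))
  for (c in seq_len(k_categories)) {
    sites <- which(cat_of == c)
    if (!length(sites)) next
    block <- phangorn::simSeq(tree, l = length(sites), type = "DNA",
                              rate = rates[c])
    m <- toupper(as.character(block))
    aln[, sites] <- m[rownames(aln), , drop = FALSE]
  }
  attr(aln, "rate_category") <- cat_of
  attr(aln, "category_rates") <- rates
  aln
}

#' Simulate a collection of loci with optional gene-tree discordance
#'
#' Each locus evolves on the species tree or, with probability
#' `discordance_prob`, on a copy perturbed by one random
#' nearest-neighbour interchange ([phangorn::rNNI()]). The true gene tree
#' is returned per locus for oracle checks.
#'
#' @param species_tree `phylo` with branch lengths.
#' @param config a [sim_config()]; its seed drives the whole collection.
#' @return named list of loci; each a list with `alignment`, `tree`, and
#'   logical `discordant`.
#' @export
sim_locus_collection <- function(species_tree, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  loci <- vector("list", config$n_loci)
  names(loci) <- sprintf("locus%03d", seq_len(config$n_loci))
  for (i in seq_len(config$n_loci)) {
    disc <- runif(1L) < config$discordance_prob
    gt <- if (disc) phangorn::rNNI(species_tree, 1L) else species_tree
    aln <- sim_alignment(gt, config$sites_per_locus, config$gamma_shape,
                         config$k_categories)
    loci[[i]] <- list(alignment = aln, tree = gt, discordant = disc)
  }
  loci
}

## General two-state transition matrix with gain rate a (susceptible ->
## tolerant) and loss rate b; rows/cols ordered (tolerant, susceptible).
.two_state_P <- function(a, b, t) {
  s <- a + b
  e <- exp(-s * t)
  matrix(c(a / s + b / s * e, b / s - b / s * e,
           a / s - a / s * e, b / s + a / s * e),
         2L, 2L, byrow = TRUE,
         dimnames = list(TRAIT_STATES, TRAIT_STATES))
}

#' Simulate a binary trait history on a tree
#'
#' States evolve along branches under a two-state Markov chain with gain
#' rate `r01` (susceptible -> tolerant) and loss rate `r10`; the root
#' state is drawn from `root_dist`. True internal states are returned for
#' recovery tests.
#'
#' @param tree `phylo` with branch lengths.
#' @param r01,r10 transition rates (> 0).
#' @param root_dist root distribution over (tolerant, susceptible).
#' @param seed optional RNG seed.
#' @return list with `tip_states` (named vector over tips), `node_states`
#'   (true states at internal nodes, named `node<N>`), and the reordered
#'   `tree`.
#' @export
sim_binary_trait <- function(tree, r01, r10, root_dist = c(0.5, 0.5),
                             seed = NULL) {
  if (r01 <= 0 || r10 <= 0) stop("trait rates must be positive")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  ntot <- ntip + ape::Nnode(tr)
  state <- integer(ntot)
  root <- tr$edge[nrow(tr$edge), 1L]
  state[root] <- 1L + (runif(1L) >= root_dist[1L] / sum(root_dist))
  for (k in rev(seq_len(nrow(tr$edge)))) { # preorder: parents first
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    P <- .two_state_P(r01, r10, tr$edge.length[k])
    ## row index: state[p] over (tolerant, susceptible); transition rates
    ## act on the underlying susceptible/tolerant coding
    pr <- P[state[p], ]
    state[ch] <- 1L + (runif(1L) >= pr[1L])
  }
  tip_states <- setNames(TRAIT_STATES[state[seq_len(ntip)]], tr$tip.label)
  node_states <- setNames(TRAIT_STATES[state[seq(ntip + 1L, ntot)]],
                          paste0("node", seq(ntip + 1L, ntot)))
  list(tip_states = tip_states, node_states = node_states, tree = tr)
}

#' Simulate vial-level survival counts for one species
#'
#' Control vials draw survivors from `Binomial(larvae, p0)`; toxin vials
#' from `Binomial(larvae, plogis(qlogis(p0) + beta))`.
#'
#' @param species species label.
#' @param p0 control survival probability in (0, 1).
#' @param beta toxin effect on the logit scale.
#' @param n_vials replicate vials per arm (default 5).
#' @param larvae_per_vial larvae placed per vial (default 20).
#' @param dose toxin dose label for the treated arm (default 50).
#' @param seed optional RNG seed.
#' @return survival-record data frame (both arms).
#' @export
sim_survival <- function(species, p0, beta, n_vials = 5L,
                         larvae_per_vial = 20L, dose = 50, seed = NULL) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p1 <- plogis(qlogis(p0) + beta)
  df <- data.frame(
    species = species,
    dose = rep(c(0, dose), each = n_vials),
    vial = rep(seq_len(n_vials), 2L),
    n_larvae = larvae_per_vial,
    n_survived = c(rbinom(n_vials, larvae_per_vial, p0),
                   rbinom(n_vials, larvae_per_vial, p1)))
  validate_survival_records(df)
}
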