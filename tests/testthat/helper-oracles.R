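# Independent brute-force oracles used across the suite. These stay on
# slow, transparent code paths (pure R, exhaustive enumeration,
# path-length quartet extraction) so they never share machinery with the
# implementations they check.

aln_from_sites <- function(site_strings, taxa = NULL) {
  # site_strings: one string per SITE, one character per taxon
  m <- do.call(cbind, lapply(site_strings, function(s) strsplit(s, "")[[1]]))
  if (is.null(taxa)) taxa <- letters[seq_len(nrow(m))]
  rownames(m) <- taxa
  as_alignment(m)
}

random_alignment <- function(n_taxa, n_sites, miss_prob = 0) {
  chars <- sample(c("A", "C", "G", "T"), n_taxa * n_sites, replace = TRUE)
  if (miss_prob > 0) {
    hit <- runif(n_taxa * n_sites) < miss_prob
    chars[hit] <- sample(c("-", "N", "?"), sum(hit), replace = TRUE)
  }
  m <- matrix(chars, n_taxa, n_sites)
  rownames(m) <- paste0("t", seq_len(n_taxa))
  m
}

# TIGER scores by direct double loop over the exported pure-R operations.
tiger_oracle <- function(aln) {
  n <- ncol(aln)
  parts <- lapply(seq_len(n), function(i) site_partition(aln, i))
  vapply(seq_len(n), function(i) {
    mean(vapply(setdiff(seq_len(n), i), function(j)
      partition_agreement(parts[[i]], parts[[j]]), numeric(1)))
  }, numeric(1))
}

# Quartet topology from path lengths with unit branch lengths: the
# pairing with the smallest distance sum is the split (four-point
# condition); ties mean unresolved.
quartet_topo_oracle <- function(tree, four) {
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  d <- ape::cophenetic.phylo(tr)[four, four]
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  w <- which(sums == min(sums))
  if (length(w) > 1) 0L else w
}

quartet_score_oracle <- function(candidate, gene_trees) {
  total <- 0L
  for (gt in gene_trees) {
    quads <- combn(sort(gt$tip.label), 4)
    for (q in seq_len(ncol(quads))) {
      tg <- quartet_topo_oracle(gt, quads[, q])
      if (tg > 0L && tg == quartet_topo_oracle(candidate, quads[, q]))
        total <- total + 1L
    }
  }
  total
}

# Exact marginal posteriors by summing over every internal labelling.
marginal_oracle <- function(tree, traits, r, root_dist = c(0.5, 0.5)) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- ape::Ntip(tree)
  ntot <- nt + tree$Nnode
  tipidx <- match(traits[tree$tip.label], TRAIT_STATES)
  ints <- seq(nt + 1, ntot)
  root <- tree$edge[nrow(tree$edge), 1]
  post <- matrix(0, length(ints), 2)
  grid <- as.matrix(expand.grid(rep(list(1:2), length(ints))))
  for (g in seq_len(nrow(grid))) {
    s <- integer(ntot)
    s[seq_len(nt)] <- tipidx
    s[ints] <- grid[g, ]
    pr <- root_dist[s[root]]
    for (k in seq_len(nrow(tree$edge))) {
      P <- transition_probability(r, tree$edge.length[k])
      pr <- pr * P[s[tree$edge[k, 1]], s[tree$edge[k, 2]]]
    }
    for (i in seq_along(ints))
      post[i, grid[g, i]] <- post[i, grid[g, i]] + pr
  }
  dimnames(post) <- list(ints, TRAIT_STATES)
  post / rowSums(post)
}

# Minimum transitions / minimum losses by enumerating internal labellings.
sankoff_oracle <- function(tree, traits, root_state = "tolerant") {
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- ape::Ntip(tree)
  ntot <- nt + tree$Nnode
  tipidx <- match(traits[tree$tip.label], TRAIT_STATES)
  ints <- seq(nt + 1, ntot)
  root <- tree$edge[nrow(tree$edge), 1]
  rs <- match(root_state, TRAIT_STATES)
  best_t <- Inf; best_l <- Inf
  grid <- as.matrix(expand.grid(rep(list(1:2), length(ints))))
  for (g in seq_len(nrow(grid))) {
    s <- integer(ntot)
    s[seq_len(nt)] <- tipidx
    s[ints] <- grid[g, ]
    if (s[root] != rs) next
    tt <- 0L; ll <- 0L
    for (k in seq_len(nrow(tree$edge))) {
      a <- s[tree$edge[k, 1]]; b <- s[tree$edge[k, 2]]
      if (a != b) {
        tt <- tt + 1L
        if (a == 1L && b == 2L) ll <- ll + 1L
      }
    }
    if (tt < best_t || (tt == best_t && ll < best_l)) {
      best_t <- tt; best_l <- ll
    }
  }
  list(transitions = best_t, losses = best_l)
}

# Firth estimates for the saturated two-arm binary design: add 1/2 to
# every cell of the 2x2 table.
firth_half_cell <- function(k0, n0, k1, n1) {
  b0 <- log((k0 + 0.5) / (n0 - k0 + 0.5))
  b1 <- log((k1 + 0.5) / (n1 - k1 + 0.5)) - b0
  c(b0, b1)
}

random_traits <- function(tree) {
  setNames(sample(TRAIT_STATES, ape::Ntip(tree), replace = TRUE),
           tree$tip.label)
}
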