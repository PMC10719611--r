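## Desk-scale tree estimation: Jukes-Cantor distances + neighbor joining
## with nonparametric bootstrap support for per-job trees, and a
## quartet-score species tree (exact enumeration for small taxon sets,
## stepwise-addition heuristic above that) standing in for a full
## coalescent species-tree analysis.

#' Jukes-Cantor pairwise distances
#'
#' `d = -(3/4) log(1 - (4/3) p)` with `p` the mismatch fraction over
#' shared non-missing sites. Pairs with `p >= 0.75` are flagged saturated
#' and set to `ceiling`.
#'
#' @param aln alignment matrix with >= 2 taxa.
#' @param ceiling distance assigned to saturated pairs (default 5).
#' @return object of class `jc_dist`: list with `distance`, `shared` and
#'   `saturated` matrices.
#' @export
jc_distance <- function(aln, ceiling = 5) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2L) stop("need >= 2 taxa")
  taxa <- rownames(aln)
  obs <- !matrix(is_missing_char(aln), n, ncol(aln))
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  S <- matrix(ncol(aln), n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    sh <- obs[i, ] & obs[j, ]
    S[i, j] <- S[j, i] <- sum(sh)
    if (!any(sh))
      stop("no shared non-missing sites between '", taxa[i], "' and '",
           taxa[j], "'")
    p <- mean(aln[i, sh] != aln[j, sh])
    if (p >= 0.75) {
      sat[i, j] <- sat[j, i] <- TRUE
      d <- ceiling
    } else d <- -0.75 * log(1 - 4 * p / 3)
    D[i, j] <- D[j, i] <- d
  }
  structure(list(distance = D, shared = S, saturated = sat),
            class = "jc_dist")
}

#' @export
print.jc_dist <- function(x, ...) {
  cat("Jukes-Cantor distances over", nrow(x$distance), "taxa")
  if (any(x$saturated)) cat(" (", sum(x$saturated) / 2, " saturated pairs)", sep = "")
  cat("\n")
  print(round(x$distance, 4))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths
#' are clamped to zero with a warning. The result is unrooted.
#'
#' @param D `jc_dist` object or symmetric distance matrix (>= 3 taxa).
#' @return unrooted `phylo` object.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "jc_dist")) D <- D$distance
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs >= 3 taxa")
  tree <- ape::nj(D)
  if (any(tree$edge.length < 0)) {
    warning("negative branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and attaches to each internal branch of the reference tree
#' the percentage of replicates containing its bipartition.
#'
#' @param aln alignment with >= 4 taxa.
#' @param n_reps number of bootstrap replicates (default 100); 0 returns
#'   the reference tree without supports.
#' @param seed optional RNG seed.
#' @param ceiling saturation ceiling passed to [jc_distance()].
#' @return reference NJ `phylo` with percentage supports in `node.label`;
#'   the full replicate split-frequency table is attached as attribute
#'   `"split_freqs"`.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = NULL, ceiling = 5) {
  aln <- as_alignment(aln)
  if (nrow(aln) < 4L) stop("bootstrap support needs >= 4 taxa")
  ref <- neighbor_joining(jc_distance(aln, ceiling))
  if (n_reps == 0L) return(ref)
  if (!is.null(seed)) set.seed(seed)
  keys <- character(0)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(aln), replace = TRUE)
    tb <- neighbor_joining(jc_distance(aln[, cols, drop = FALSE], ceiling))
    keys <- c(keys, bipartitions(tb))
  }
  freqs <- table(keys)
  sk <- split_keys(ref, with_nodes = TRUE)
  lab <- rep("", ape::Nnode(ref))
  cnt <- as.integer(freqs[sk$key])
  cnt[is.na(cnt)] <- 0L
  lab[sk$node - ape::Ntip(ref)] <- as.character(round(100 * cnt / n_reps))
  ref$node.label <- lab
  attr(ref, "split_freqs") <- freqs
  ref
}

## Quartet topology codes for every 4-leaf subset of a tree's taxa.
## Subsets are combn() columns over the sorted tip labels; codes:
## 1 = wx|yz, 2 = wy|xz, 3 = wz|xy for the sorted subset (w,x,y,z),
## 0 = unresolved (multifurcation).
.quartet_codes <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  if (n < 4L) return(list(keys = character(0), codes = integer(0)))
  pp <- ape::prop.part(tree)
  memb <- matrix(FALSE, length(pp), n)
  for (r in seq_along(pp))
    memb[r, match(tree$tip.label[pp[[r]]], tips)] <- TRUE
  sz <- rowSums(memb)
  memb <- memb[sz >= 2L & sz <= n - 2L, , drop = FALSE]
  subs <- combn(n, 4L)
  codes <- integer(ncol(subs))
  for (q in seq_len(ncol(subs))) {
    m <- memb[, subs[, q], drop = FALSE]
    r <- which(rowSums(m) == 2L)
    if (!length(r)) next
    pat <- m[r[1L], ]
    codes[q] <- if (pat[1L]) {
      if (pat[2L]) 1L else if (pat[3L]) 2L else 3L
    } else {
      if (pat[2L]) (if (pat[3L]) 3L else 2L) else 1L
    }
  }
  keys <- apply(subs, 2L, function(s) paste(tips[s], collapse = "|"))
  list(keys = keys, codes = codes)
}

#' Quartet score of a candidate species tree against gene trees
#'
#' Number of (gene tree, 4-taxon subset) pairs whose induced quartet
#' topology matches the candidate's. Unresolved gene-tree quartets count
#' for no topology; gene-tree leaf sets may be subsets of the candidate's.
#'
#' @param candidate `phylo` species-tree candidate.
#' @param gene_trees list of `phylo` gene trees.
#' @return integer score.
#' @export
quartet_score <- function(candidate, gene_trees) {
  cand <- .quartet_codes(candidate)
  total <- 0L
  for (gt in gene_trees) {
    if (!all(gt$tip.label %in% candidate$tip.label))
      stop("gene-tree leaf set is not a subset of the candidate's")
    g <- .quartet_codes(gt)
    if (!length(g$codes)) next
    m <- match(g$keys, cand$keys)
    total <- total + sum(g$codes > 0L & cand$codes[m] == g$codes)
  }
  total
}

## Tally of resolved gene-tree quartet topologies over combn(sort(taxa), 4).
.quartet_tally <- function(gene_trees, taxa) {
  taxa <- sort(taxa)
  keys <- apply(combn(length(taxa), 4L), 2L,
                function(s) paste(taxa[s], collapse = "|"))
  tal <- matrix(0L, length(keys), 3L, dimnames = list(keys, NULL))
  for (gt in gene_trees) {
    g <- .quartet_codes(gt)
    ok <- g$codes > 0L
    if (!any(ok)) next
    i <- match(g$keys[ok], keys)
    idx <- cbind(i, g$codes[ok])
    tal[idx] <- tal[idx] + 1L
  }
  tal
}

.tally_score <- function(codes, keys, tal) {
  ok <- codes > 0L
  if (!any(ok)) return(0L)
  i <- match(keys[ok], rownames(tal))
  sum(tal[cbind(i, codes[ok])])
}

#' Exact maximum-quartet-score species tree
#'
#' Enumerates every unrooted binary topology on the union of gene-tree
#' taxa and returns the one maximizing [quartet_score()]; ties resolved by
#' the lexicographically smallest Newick string. Feasible only for small
#' taxon sets; beyond `max_taxa` use [greedy_quartet_species_tree()].
#'
#' @param gene_trees list of `phylo` gene trees.
#' @param max_taxa enumeration limit (default 9).
#' @return unrooted `phylo` with attribute `"quartet_score"`.
#' @export
exact_quartet_species_tree <- function(gene_trees, max_taxa = 9L) {
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  n <- length(taxa)
  if (n < 4L) stop("need >= 4 taxa")
  if (n > max_taxa)
    stop("exhaustive search limited to ", max_taxa,
         " taxa (got ", n, "); use greedy_quartet_species_tree()")
  tal <- .quartet_tally(gene_trees, taxa)
  cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  best <- NULL; best_score <- -1L; best_nwk <- ""
  for (ci in seq_along(cands)) {
    tr <- cands[[ci]] # [[ expands the shared tip labels of the multiPhylo
    qc <- .quartet_codes(tr)
    sc <- .tally_score(qc$codes, qc$keys, tal)
    nwk <- ape::write.tree(tr)
    if (sc > best_score || (sc == best_score && nwk < best_nwk)) {
      best <- tr; best_score <- sc; best_nwk <- nwk
    }
  }
  attr(best, "quartet_score") <- best_score
  best
}

## Attach a new tip in the middle of edge `edge` (row of tree$edge).
.attach_tip <- function(tree, edge, label) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  cherry <- ape::read.tree(text = paste0("(", label, ":1,zzdummyzz:1):1;"))
  out <- ape::bind.tree(tree, cherry, where = tree$edge[edge, 2L],
                        position = 0.5)
  ape::drop.tip(out, "zzdummyzz")
}

#' Greedy maximum-quartet-score species tree
#'
#' Stepwise taxon addition: taxa are inserted in sorted-label order, each
#' at the placement maximizing the quartet score over the taxa present so
#' far (ties go to the lowest edge index). Deterministic for a fixed
#' input.
#'
#' @param gene_trees list of `phylo` gene trees (>= 4 taxa in the union).
#' @return unrooted `phylo` with attribute `"quartet_score"`.
#' @export
greedy_quartet_species_tree <- function(gene_trees) {
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  n <- length(taxa)
  if (n < 4L) stop("need >= 4 taxa")
  tal <- .quartet_tally(gene_trees, taxa)
  first4 <- taxa[1:4]
  topo <- which.max(tal[paste(first4, collapse = "|"), ])
  nwk <- switch(topo,
    sprintf("((%s:1,%s:1):1,%s:1,%s:1);", first4[1], first4[2], first4[3], first4[4]),
    sprintf("((%s:1,%s:1):1,%s:1,%s:1);", first4[1], first4[3], first4[2], first4[4]),
    sprintf("((%s:1,%s:1):1,%s:1,%s:1);", first4[1], first4[4], first4[2], first4[3]))
  tree <- ape::read.tree(text = nwk)
  for (tx in taxa[-(1:4)]) {
    best <- NULL; best_score <- -1L
    for (e in seq_len(nrow(tree$edge))) {
      cand <- .attach_tip(tree, e, tx)
      qc <- .quartet_codes(cand)
      sc <- .tally_score(qc$codes, qc$keys, tal)
      if (sc > best_score) { best <- cand; best_score <- sc }
    }
    tree <- best
  }
  qc <- .quartet_codes(tree)
  attr(tree, "quartet_score") <- .tally_score(qc$codes, qc$keys, tal)
  tree
}
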