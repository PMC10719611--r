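## Robinson-Foulds distances, classical MDS embedding, centroid-distance
## locus ranking, nested inclusion sets and the 8 x 8 support grids: the
## machinery of the site-rate sensitivity analysis.

## Canonical split keys: tips on the side not containing the reference
## taxon (first tip in sorted order), sorted and pasted. Non-trivial
## splits only (both sides >= 2 tips).
split_keys <- function(tree, with_nodes = FALSE) {
  tips <- tree$tip.label
  ref <- sort(tips)[1L]
  pp <- ape::prop.part(tree)
  nodes <- seq_along(pp) + ape::Ntip(tree)
  keys <- character(0)
  knodes <- integer(0)
  for (i in seq_along(pp)) {
    side <- tips[pp[[i]]]
    other <- setdiff(tips, side)
    if (length(side) < 2L || length(other) < 2L) next
    if (ref %in% side) side <- other
    keys <- c(keys, paste(sort(side), collapse = "|"))
    knodes <- c(knodes, nodes[i])
  }
  if (with_nodes) {
    keep <- !duplicated(keys)
    return(data.frame(node = knodes[keep], key = keys[keep],
                      stringsAsFactors = FALSE))
  }
  unique(keys)
}

#' Non-trivial bipartitions of a tree
#'
#' One canonical split per internal edge under the unrooted
#' interpretation; rooted and unrooted representations of the same
#' topology yield the same set.
#'
#' @param tree `phylo` object.
#' @return character vector of canonical split keys (tips of the side not
#'   containing the alphabetically first taxon, `|`-joined); empty for
#'   trees with fewer than 4 leaves.
#' @export
bipartitions <- function(tree) {
  if (ape::Ntip(tree) < 4L) return(character(0))
  split_keys(tree)
}

#' Robinson-Foulds distance between two trees
#'
#' Count of bipartitions present in exactly one tree (symmetric
#' difference of split sets); the normalized variant divides by the total
#' number of splits in both trees.
#'
#' @param t1,t2 `phylo` objects on identical leaf sets.
#' @param normalized divide by `|B1| + |B2|`?
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    d1 <- setdiff(t1$tip.label, t2$tip.label)
    d2 <- setdiff(t2$tip.label, t1$tip.label)
    stop("leaf sets differ; only in first: {",
         paste(d1, collapse = ","), "}, only in second: {",
         paste(d2, collapse = ","), "}")
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  d <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (normalized) {
    tot <- length(b1) + length(b2)
    return(if (tot == 0L) 0 else d / tot)
  }
  d
}

#' Pairwise Robinson-Foulds distance matrix for a tree collection
#'
#' @param trees list of `phylo` objects on one leaf set.
#' @param normalized see [rf_distance()].
#' @return symmetric numeric matrix with zero diagonal, named by
#'   `names(trees)`.
#' @export
rf_matrix <- function(trees, normalized = FALSE) {
  n <- length(trees)
  ids <- names(trees)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  bips <- lapply(trees, bipartitions)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- length(setdiff(bips[[i]], bips[[j]])) +
      length(setdiff(bips[[j]], bips[[i]]))
    if (normalized) {
      tot <- length(bips[[i]]) + length(bips[[j]])
      d <- if (tot == 0L) 0 else d / tot
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances and eigendecomposes
#' (`stats::cmdscale`). Negative eigenvalues are truncated to zero with a
#' warning; coordinates for dimensions with non-positive eigenvalues are
#' zero.
#'
#' @param D symmetric distance matrix, zero diagonal.
#' @param k embedding dimension (default 2).
#' @return numeric matrix of coordinates (`n x k`) with the eigenvalues as
#'   attribute `"eigenvalues"`.
#' @export
classical_mds <- function(D, k = 2L) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  k <- min(k, nrow(D) - 1L)
  fit <- suppressWarnings(cmdscale(D, k = max(k, 1L), eig = TRUE))
  if (any(fit$eig < -1e-8 * max(abs(fit$eig), 1)))
    warning("negative eigenvalues truncated to 0 (distances not fully Euclidean)")
  pts <- fit$points
  if (ncol(pts) < k)
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  rownames(pts) <- rownames(D)
  attr(pts, "eigenvalues") <- fit$eig
  pts
}

#' Euclidean distance of each embedded point to the centroid
#'
#' @param points coordinate matrix from [classical_mds()].
#' @return named numeric vector of distances.
#' @export
centroid_distances <- function(points) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  d <- sqrt(rowSums(sweep(points, 2L, ctr)^2))
  names(d) <- rownames(points)
  d
}

#' Rank loci by distance of their trees to the embedding centroid
#'
#' Composes [rf_matrix()], [classical_mds()] and [centroid_distances()]:
#' loci whose trees sit near the centre of tree space rank first, outlier
#' trees last. Ties are broken by locus id.
#'
#' @param trees named list of per-locus trees (one per locus).
#' @param k embedding dimension (default 2).
#' @return character vector of locus ids, ascending centroid distance.
#' @export
rank_loci <- function(trees, k = 2L) {
  ids <- names(trees)
  if (is.null(ids)) ids <- as.character(seq_along(trees))
  d <- centroid_distances(classical_mds(rf_matrix(trees), k = k))
  ids[order(d, ids)]
}

#' Nested inclusion sets from a locus ranking
#'
#' Set `k` holds the first `floor(k * N / n_sets)` loci of the ranking
#' (least outlying first); the last set holds all `N`. For `N = 489` and
#' 8 sets the sizes are 61, 122, 183, 244, 305, 366, 427, 489.
#'
#' @param ranking ordered locus ids from [rank_loci()].
#' @param n_sets number of inclusion sets (default 8).
#' @return list of `n_sets` character vectors, nested.
#' @export
make_inclusion_sets <- function(ranking, n_sets = 8L) {
  n <- length(ranking)
  if (n < n_sets) stop("need at least ", n_sets, " ranked loci, got ", n)
  sizes <- floor(seq_len(n_sets) * n / n_sets)
  sizes[n_sets] <- n
  lapply(sizes, function(s) ranking[seq_len(s)])
}

#' Build the bin-subset x inclusion-set job grid
#'
#' Crosses the cumulative bin subsets (see [cumulative_alignments()]) with
#' the nested inclusion sets: job `(k, s)` concatenates, over the loci of
#' inclusion set `s`, each locus restricted to bins `2..(k + 2)`. With the
#' defaults this yields the 64-job sensitivity grid.
#'
#' @param loci named list; each element a list with components `alignment`
#'   and `bins` (from [bin_sites()]).
#' @param ranking ordered ids of retained loci (see
#'   [filter_loci_all_bins()], [rank_loci()]).
#' @param n_bin_subsets,n_sets grid dimensions (defaults 8 x 8).
#' @param label_style how a bin subset is labelled in the job metadata:
#'   by its ending bin (default) or by the number of bins it spans.
#' @return list of jobs; each has `bin_subset`, `inclusion_set`, `label`,
#'   `loci` and the concatenated `alignment`.
#' @export
build_sensitivity_sets <- function(loci, ranking,
                                   n_bin_subsets = 8L, n_sets = 8L,
                                   label_style = c("ending_bin", "bin_count")) {
  label_style <- match.arg(label_style)
  stopifnot(all(ranking %in% names(loci)))
  sets <- make_inclusion_sets(ranking, n_sets)
  cum <- lapply(loci[ranking], function(l)
    cumulative_alignments(l$alignment, l$bins, n_bin_subsets))
  jobs <- vector("list", n_bin_subsets * n_sets)
  idx <- 0L
  for (k in seq_len(n_bin_subsets)) {
    for (s in seq_len(n_sets)) {
      ids <- sets[[s]]
      aln <- do.call(cbind, lapply(cum[ids], `[[`, k))
      idx <- idx + 1L
      jobs[[idx]] <- list(
        bin_subset = k,
        inclusion_set = s,
        label = if (label_style == "ending_bin")
          sprintf("bins2-%d_set%d", k + 2L, s)
        else sprintf("nbins%d_set%d", k + 1L, s),
        loci = ids,
        alignment = aln)
    }
  }
  names(jobs) <- vapply(jobs, function(j)
    sprintf("b%d_s%d", j$bin_subset, j$inclusion_set), character(1L))
  jobs
}

#' Branch-support grids across the sensitivity jobs
#'
#' For each monitored clade (a bipartition of the reference tree) and each
#' job tree, records the support value attached to that bipartition in the
#' job's tree, or `NA` when the clade was not recovered (rendered as 0
#' support in heatmaps).
#'
#' @param reference_tree `phylo` whose non-trivial bipartitions define the
#'   monitored clades (or pass `monitored_clades` explicitly).
#' @param trees list of annotated trees, one per job, sharing the
#'   reference leaf set; supports read from numeric `node.label`.
#' @param bin_subset,inclusion_set integer vectors parallel to `trees`.
#' @param monitored_clades optional character vector of split keys.
#' @return named list (one per clade) of `n_bin_subsets x n_sets` support
#'   matrices.
#' @export
support_grid <- function(reference_tree, trees, bin_subset, inclusion_set,
                         monitored_clades = NULL) {
  stopifnot(length(trees) == length(bin_subset),
            length(trees) == length(inclusion_set))
  if (is.null(monitored_clades))
    monitored_clades <- bipartitions(reference_tree)
  nb <- max(bin_subset)
  ns <- max(inclusion_set)
  grids <- lapply(monitored_clades, function(cl)
    matrix(NA_real_, nb, ns,
           dimnames = list(paste0("bins", seq_len(nb)),
                           paste0("set", seq_len(ns)))))
  names(grids) <- monitored_clades
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!setequal(tr$tip.label, reference_tree$tip.label))
      stop("job tree ", i, " does not share the reference leaf set")
    sk <- split_keys(tr, with_nodes = TRUE)
    sup <- suppressWarnings(as.numeric(tr$node.label))
    supp_of <- setNames(sup[sk$node - ape::Ntip(tr)], sk$key)
    for (cl in monitored_clades) {
      if (cl %in% sk$key)
        grids[[cl]][bin_subset[i], inclusion_set[i]] <- unname(supp_of[cl])
    }
  }
  grids
}
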