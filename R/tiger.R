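## TIGER-style per-site evolutionary rate scoring. Each alignment column
## induces a set partition of the taxa (taxa sharing a character share a
## block; missing taxa excluded). A site's rate score is the mean agreement
## between its partition and every other site's partition: conserved sites
## agree with everything (score 1), fast sites agree with little.

#' Set partition of taxa induced by one alignment column
#'
#' @param aln alignment matrix.
#' @param i site index (1-based).
#' @return named list of character vectors: blocks of taxa keyed by the
#'   observed character; taxa with a missing character are excluded. An
#'   all-missing column yields a partition with zero blocks.
#' @export
site_partition <- function(aln, i) {
  aln <- as_alignment(aln)
  if (i < 1L || i > ncol(aln)) stop("site index out of range: ", i)
  col <- aln[, i]
  keep <- !is_missing_char(col)
  split(rownames(aln)[keep], col[keep])
}

#' Agreement between two site partitions
#'
#' The score is the fraction of blocks of `p_j` that nest inside a single
#' block of `p_i`. Blocks are restricted to taxa present in `p_i` before
#' the subset check, so missing data never breaks nesting; an empty
#' partition (or empty restriction) scores 1 by convention.
#'
#' @param p_i,p_j partitions from [site_partition()].
#' @return score in `[0, 1]`.
#' @export
partition_agreement <- function(p_i, p_j) {
  if (!length(p_j)) return(1)
  block_of <- rep(seq_along(p_i), lengths(p_i))
  names(block_of) <- unlist(p_i, use.names = FALSE)
  nested <- vapply(p_j, function(b) {
    ids <- block_of[b[b %in% names(block_of)]]
    length(ids) == 0L || length(unique(ids)) == 1L
  }, logical(1L))
  mean(nested)
}

## taxa x sites integer codes for the compiled kernel: 0-based block id
## per taxon per site, -1 for missing.
site_codes <- function(aln) {
  codes <- matrix(-1L, nrow(aln), ncol(aln))
  nblocks <- integer(ncol(aln))
  for (s in seq_len(ncol(aln))) {
    col <- aln[, s]
    keep <- !is_missing_char(col)
    f <- factor(col[keep])
    codes[keep, s] <- as.integer(f) - 1L
    nblocks[s] <- nlevels(f)
  }
  list(codes = codes, nblocks = nblocks)
}

#' TIGER rate scores for every site of an alignment
#'
#' `score(i)` is the mean of [partition_agreement()] between site `i` and
#' every other site. Invariant sites (at most one observed character)
#' score exactly 1; lower scores indicate faster-evolving sites.
#'
#' @param aln alignment with at least two sites.
#' @return numeric vector of per-site scores in `[0, 1]`.
#' @export
tiger_rates <- function(aln) {
  aln <- as_alignment(aln)
  if (ncol(aln) < 2L) stop("rate scoring needs an alignment with >= 2 sites")
  sc <- site_codes(aln)
  .tiger_scores_cpp(sc$codes, sc$nblocks)
}

#' Assign sites to ten rate bins
#'
#' Bin 1 holds invariant sites (ignoring missing data; all-missing columns
#' are treated as invariant). Variant sites are ranked by descending rate
#' score (ties broken by site index) and split into `n_bins - 1`
#' equal-frequency bins 2..`n_bins`, so the last bin holds the
#' fastest-evolving sites.
#'
#' @param rates scores from [tiger_rates()].
#' @param aln the alignment the scores were computed from.
#' @param n_bins total number of bins (default 10).
#' @return integer vector of per-site bin labels in `1..n_bins`.
#' @export
bin_sites <- function(rates, aln, n_bins = 10L) {
  aln <- as_alignment(aln)
  stopifnot(length(rates) == ncol(aln), n_bins >= 2L)
  inv <- invariant_sites(aln)
  bins <- rep(1L, ncol(aln))
  vs <- which(!inv)
  if (length(vs)) {
    v <- length(vs)
    ord <- vs[order(-rates[vs], vs)]
    ranks <- integer(v)
    ranks[match(ord, vs)] <- seq_len(v)
    bins[vs] <- 2L + as.integer(floor((ranks - 1L) * (n_bins - 1L) / v))
  }
  bins
}

#' Cumulative-bin alignments
#'
#' Builds the eight alignments used by the sensitivity analysis: subset
#' `k` contains the sites of bins `2..(k + 2)`, i.e. `{2,3}`, `{2,3,4}`,
#' ..., `{2..10}`. Bin 1 (invariant sites) is never included. Original
#' site order is preserved and the site sets are nested.
#'
#' @param aln alignment matrix.
#' @param bins labels from [bin_sites()].
#' @param n_subsets number of cumulative subsets (default 8).
#' @return list of `n_subsets` alignments; each carries the included site
#'   indices as attribute `"sites"`.
#' @export
cumulative_alignments <- function(aln, bins, n_subsets = 8L) {
  aln <- as_alignment(aln)
  stopifnot(length(bins) == ncol(aln))
  lapply(seq_len(n_subsets), function(k) {
    sites <- which(bins >= 2L & bins <= k + 2L)
    sub <- aln[, sites, drop = FALSE]
    attr(sub, "sites") <- sites
    sub
  })
}

#' Retain loci with sites in every rate bin
#'
#' A locus is kept only if each bin `1..n_bins` contains at least one of
#' its sites.
#'
#' @param bin_list named list of per-locus bin assignments.
#' @param n_bins number of bins (default 10).
#' @return character vector of retained locus ids.
#' @export
filter_loci_all_bins <- function(bin_list, n_bins = 10L) {
  if (is.null(names(bin_list))) names(bin_list) <- seq_along(bin_list)
  keep <- vapply(bin_list, function(b) all(seq_len(n_bins) %in% b), logical(1L))
  names(bin_list)[keep]
}

#' Per-locus site rate table
#'
#' Convenience wrapper producing the `site, score, bin` report (1-based
#' site indices) for one locus.
#' @param aln alignment matrix.
#' @param n_bins number of bins (default 10).
#' @export
tiger_table <- function(aln, n_bins = 10L) {
  rates <- tiger_rates(aln)
  data.frame(site = seq_along(rates), score = rates,
             bin = bin_sites(rates, aln, n_bins))
}
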