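## Alignments are plain character matrices: rows = taxa (unique rownames),
## columns = sites, characters in {A,C,G,T} plus the missing tokens below.

#' Missing-data tokens recognised in alignments
#'
#' Gap, ambiguous base and unknown character are all treated as a single
#' internal "missing" convention by the rate-scoring stage.
#' @export
MISSING_TOKENS <- c("-", "N", "?")

DNA_ALPHABET <- c("A", "C", "G", "T", MISSING_TOKENS)

#' Construct and validate an alignment
#'
#' @param x character matrix (taxa x sites) or list of equal-length
#'   character vectors named by taxon.
#' @return validated character matrix with uppercase characters.
#' @export
as_alignment <- function(x) {
  if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1L) {
      bad <- names(x)[which(lens != lens[1L])[1L]]
      stop("ragged alignment: sequence for taxon '", bad,
           "' has length ", lens[[bad]], ", expected ", lens[1L])
    }
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x) || !is.character(x))
    stop("alignment must be a character matrix")
  x[] <- toupper(x)
  validate_alignment(x)
  x
}

validate_alignment <- function(aln) {
  taxa <- rownames(aln)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("alignment taxa must be named and non-empty")
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  bad <- setdiff(unique(as.vector(aln)), DNA_ALPHABET)
  if (length(bad))
    stop("characters outside alphabet {A,C,G,T,-,N,?}: ",
         paste(bad, collapse = ", "))
  invisible(aln)
}

is_missing_char <- function(x) x %in% MISSING_TOKENS

## TRUE for columns with at most one distinct non-missing character
## (all-missing columns count as invariant: they carry no rate signal).
invariant_sites <- function(aln) {
  apply(aln, 2L, function(col) {
    obs <- unique(col[!is_missing_char(col)])
    length(obs) <= 1L
  })
}
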