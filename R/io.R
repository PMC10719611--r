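## Readers and writers for the formats the pipeline touches: FASTA locus
## alignments, Newick trees (support values as internal-node labels, the
## FigTree/RAxML convention), and delimited survival / trait tables.
## All readers reject invariant-violating inputs instead of repairing them.

#' Read a FASTA alignment
#'
#' @param path path to a multi-record FASTA file.
#' @return character matrix (taxa x sites), uppercase, characters restricted
#'   to `{A,C,G,T,-,N,?}`. Record order is preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) stop("no records in FASTA file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             set.attributes = FALSE)
  if (!length(recs)) stop("no records in FASTA file: ", path)
  as_alignment(lapply(recs, as.character))
}

#' Write a FASTA alignment
#'
#' One record per taxon, sequence lines wrapped at 80 columns.
#'
#' @param aln alignment matrix (see [as_alignment()]).
#' @param path output path.
#' @export
write_fasta <- function(aln, path) {
  aln <- as_alignment(aln)
  seqinr::write.fasta(sequences = lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                      names = rownames(aln), file.out = path, nbchar = 80)
  invisible(path)
}

#' Parse a Newick tree string
#'
#' Branch lengths follow `:`; numeric internal-node labels are interpreted
#' as branch support values and kept in `node.label`.
#'
#' @param text single Newick statement terminated by `;`.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at character ", i, " of Newick string")
    }
  }
  if (depth > 0L)
    stop("unbalanced '(' in Newick string: ", depth, " unclosed at end")
  if (!grepl(";", text))
    stop("Newick statement must be terminated by ';' (offset ", nchar(text), ")")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree in input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths in Newick input")
  tree
}

#' Read a Newick tree from a file
#' @param path file containing one Newick statement.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a tree in Newick format
#'
#' @param tree `phylo` object; `node.label` (support values) and branch
#'   lengths are preserved.
#' @param path output path, or `NULL` to return the string.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

detect_delim <- function(header) if (grepl("\t", header)) "\t" else ","

#' Read a vial-level survival table
#'
#' Comma- or tab-delimited (auto-detected from the header) with columns
#' `species, dose, vial, n_larvae, n_survived`; one row per vial.
#'
#' @param path path to the table.
#' @return validated data frame.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delim(readLines(path, n = 1L))
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("species", "dose", "vial", "n_larvae", "n_survived")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  validate_survival_records(df[need])
}

#' Validate survival records
#'
#' Enforces `0 <= n_survived <= n_larvae` and `dose >= 0`, naming the
#' offending row on failure.
#' @param df data frame with survival-record columns.
#' @export
validate_survival_records <- function(df) {
  if (any(df$dose < 0)) stop("negative dose in row ", which(df$dose < 0)[1L])
  if (any(df$n_larvae < 1)) stop("no larvae in row ", which(df$n_larvae < 1)[1L])
  bad <- which(df$n_survived < 0 | df$n_survived > df$n_larvae)
  if (length(bad))
    stop("n_survived outside [0, n_larvae] in row ", bad[1L],
         " (species ", df$species[bad[1L]], ")")
  df
}

#' Read a species -> binary tolerance state table
#'
#' Delimited table with columns `species` and `state`; states may be
#' `tolerant`/`susceptible`/`missing` or the assay shorthand `A`/`B`/`NT`.
#'
#' @param path path to the table.
#' @return named character vector of states (`NA` where missing), usable
#'   directly by the reconstruction functions.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delim(readLines(path, n = 1L))
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("species", "state") %in% names(df)))
    stop("trait table needs columns 'species' and 'state'")
  if (anyDuplicated(df$species))
    stop("duplicate species in trait table: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  map <- c(A = "tolerant", B = "susceptible", NT = NA_character_,
           tolerant = "tolerant", susceptible = "susceptible",
           missing = NA_character_)
  st <- df$state
  unknown <- setdiff(st, names(map))
  if (length(unknown))
    stop("unknown trait states: ", paste(unknown, collapse = ", "))
  setNames(unname(map[st]), df$species)
}
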