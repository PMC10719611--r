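## Bundled reference tables: the published larva-to-adult survival
## proportions for the 16 newly assayed mushroom-feeding Drosophila
## species (doses 0 and 50 ug/g alpha-amanitin, five replicate vials of
## 15-25 larvae per arm), and the tolerance states of all 48 study
## species (the two D. subquinaria strains counted separately).

#' Published survival-assay summary for 16 Drosophila species
#'
#' Per species: species group, larvae placed per vial, pooled
#' larva-to-adult survival proportions on control and 50 ug/g
#' alpha-amanitin diets, and the reported chi-square statistic and
#' p-value (df = 1) kept as printed for reference.
#'
#' @return data frame with one row per assayed species.
#' @export
amanitin_assay <- function() {
  read.table(system.file("extdata", "amanitin_assay.tsv",
                         package = "phylotox"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Tolerance states of the 48 study species
#'
#' Species group and alpha-amanitin tolerance category for every taxon of
#' the radiation-wide phylogeny: `A` (at least 10% survival at 50 ug/g),
#' `B` (less than 10%), or `NT` (not tested).
#'
#' @param as_traits return a named state vector usable by the
#'   reconstruction functions (`tolerant`/`susceptible`/`NA`) instead of
#'   the raw table?
#' @return data frame (default) or named character vector.
#' @export
species_tolerance <- function(as_traits = FALSE) {
  df <- read.table(system.file("extdata", "species_tolerance.tsv",
                               package = "phylotox"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!as_traits) return(df)
  map <- c(A = "tolerant", B = "susceptible", NT = NA_character_)
  setNames(unname(map[df$state]), df$species)
}
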