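## Bundled published comparison values for the two Saccharum ancestor
## plastomes (S. officinarum Badila, MN204507; S. spontaneum Yunnan 83-184,
## MN204508), shipped as plain-text tables under inst/extdata. They serve
## as worked-example inputs and as reference points for the validation
## suite; the package never needs the accession sequences themselves for
## these tables.

pub_path <- function(file) {
  system.file("extdata", file, package = "plastcompare", mustWork = TRUE)
}

read_pub <- function(file) {
  utils::read.delim(pub_path(file), comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Published codon usage of the two Saccharum ancestor plastomes
#'
#' Per-codon counts and RSCU values as printed for S. officinarum (Badila)
#' and S. spontaneum (Yunnan 83-184). AUA and GUG appear both under their
#' standard amino acid and, as recoded start codons, under Met.
#'
#' @param species `"officinarum"` or `"spontaneum"`, or `"both"` for the
#'   full table.
#' @return data.frame; for a single species the columns are `aa`, `codon`,
#'   `count`, `rscu_published`.
#' @export
published_codon_usage <- function(species = c("both", "officinarum",
                                              "spontaneum")) {
  species <- match.arg(species)
  tab <- read_pub("saccharum_codon_usage.tsv")
  if (species == "both") return(tab)
  data.frame(aa = tab$aa, codon = tab$codon,
             count = tab[[paste0("count_", species)]],
             rscu_published = tab[[paste0("rscu_", species)]])
}

#' Published coding SNP loci between the two ancestor plastomes
#'
#' The 24 published substitution loci of the S. spontaneum plastome
#' referenced to S. officinarum, with gene-relative position (1-based on
#' the spliced coding sequence) and the reference/alternate codons and
#' amino acids.
#'
#' @return data.frame with `gene_order`, `gene`, `position`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`.
#' @export
published_snp_loci <- function() {
  read_pub("saccharum_snp_loci.tsv")
}

#' Published quadripartite region lengths of the two ancestor plastomes
#'
#' @return data.frame with `species`, `accession`, `total`, `lsc`, `ssc`,
#'   `irb`, `ira` (bp).
#' @export
published_region_lengths <- function() {
  read_pub("saccharum_plastome_regions.tsv")
}

#' Published microsatellites of the two ancestor plastomes (strict preset)
#'
#' The published SSR complement under the strict scanning preset, with
#' compound formations decomposed into constituents (grouped by the
#' `compound` column).
#'
#' @param species `"officinarum"`, `"spontaneum"` or `"both"`.
#' @return data.frame with `species`, `motif`, `repeats`, `start`, `end`,
#'   `compound`.
#' @export
published_ssr_loci <- function(species = c("both", "officinarum",
                                           "spontaneum")) {
  species <- match.arg(species)
  tab <- read_pub("saccharum_ssr_loci.tsv")
  if (species != "both") tab <- tab[tab$species == species, ]
  rownames(tab) <- NULL
  tab
}
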