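#' @keywords internal
"_PACKAGE"

## Internal coordinate convention: 1-based inclusive throughout (the
## R/Bioconductor convention); GFF3 files already use it, so no conversion
## happens at file boundaries. Report writers state the convention in their
## headers.

#' Construct a genome record
#'
#' A `genome_record` holds one plastome sequence: an identifier, the
#' uppercased nucleotide string, whether the molecule is circular, and its
#' length in bp. Sequences are restricted to IUPAC nucleotide codes; `U` is
#' mapped to `T` on input.
#'
#' @param id Character identifier.
#' @param sequence Nucleotide string (case-insensitive; `U` accepted).
#' @param circular Logical; plastomes are circular molecules.
#' @return An object of class `genome_record` with fields `id`, `sequence`,
#'   `circular` and `length`.
#' @examples
#' g <- genome_record("toy", "acgtacgt")
#' g$length
#' @export
genome_record <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  seq <- toupper(sequence)
  seq <- chartr("U", "T", seq)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", seq)
  if (nzchar(bad)) {
    stop("sequence for '", id, "' contains non-IUPAC characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(id = id, sequence = seq, circular = isTRUE(circular),
         length = nchar(seq)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp (%s)\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a gene feature
#'
#' A strand-aware, possibly multi-exon gene model. Exons are 1-based
#' inclusive `(start, end)` intervals in genome coordinates, listed in
#' genomic order; for minus-strand features the translation order is the
#' reverse, handled by [extract_cds()].
#'
#' @param gene_name Gene symbol (e.g. `"ndhF"`).
#' @param feature_type One of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of `(start, end)` pairs.
#' @param trans_spliced Logical; `TRUE` for rps12-style features whose exons
#'   come from separate transcripts.
#' @param copy_index Integer distinguishing IR-duplicated copies of the same
#'   gene (1 for unique genes).
#' @param partial Logical; a partial CDS is exempt from the length-multiple-
#'   of-3 integrity check.
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(gene_name, feature_type = "CDS", strand = "+",
                         exons, trans_spliced = FALSE, copy_index = 1L,
                         partial = FALSE) {
  stopifnot(feature_type %in% c("CDS", "tRNA", "rRNA"))
  if (!strand %in% c("+", "-")) {
    stop("unknown strand symbol '", strand, "' for gene ", gene_name,
         call. = FALSE)
  }
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  dimnames(exons) <- list(NULL, c("start", "end"))
  if (nrow(exons) == 0L || any(exons[, "end"] < exons[, "start"])) {
    stop("empty or inverted exon interval in gene ", gene_name, call. = FALSE)
  }
  structure(
    list(gene_name = gene_name, feature_type = feature_type, strand = strand,
         exons = exons, trans_spliced = isTRUE(trans_spliced),
         copy_index = as.integer(copy_index), partial = isTRUE(partial)),
    class = "gene_feature"
  )
}

#' Construct an annotation set
#'
#' @param genome_id Identifier of the genome the features belong to.
#' @param features List of [gene_feature()] objects. `gene_name` +
#'   `copy_index` must be unique within the set.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genome_id, features) {
  stopifnot(all(vapply(features, inherits, logical(1), "gene_feature")))
  key <- vapply(features, function(f) {
    paste0(f$gene_name, "#", f$copy_index)
  }, character(1))
  if (anyDuplicated(key)) {
    stop("duplicate gene_name/copy_index in annotation set: ",
         paste(key[duplicated(key)], collapse = ", "), call. = FALSE)
  }
  structure(list(genome_id = genome_id, features = features),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  types <- table(vapply(x$features, `[[`, character(1), "feature_type"))
  cat(sprintf("<annotation_set> %s: %d features (%s)\n", x$genome_id,
              length(x$features),
              paste(names(types), types, sep = "=", collapse = ", ")))
  invisible(x)
}

## reverse complement for plain character strings (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
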