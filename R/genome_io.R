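#' Read a FASTA file of genome sequences
#'
#' One [genome_record()] is returned per FASTA entry. Sequences are
#' uppercased and `U` is mapped to `T`; characters outside the IUPAC
#' nucleotide alphabet raise a format error.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, applied to every record (plastomes are circular).
#' @return List of `genome_record` objects, named by identifier.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  recs <- lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), circular = circular)
  })
  names(recs) <- ids
  recs
}

#' Write genome records to FASTA
#'
#' @param genomes A `genome_record` or list of them.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$id), con)
    starts <- seq(1L, g$length, by = width)
    writeLines(substring(g$sequence, starts,
                         pmin(starts + width - 1L, g$length)), con)
  }
  invisible(path)
}

#' Read gene annotations
#'
#' Supports two dialects: `"gff3"` (9-column GFF, CDS segments grouped by
#' their `Parent` attribute) and `"feature_table"` (a flat TSV with one row
#' per exon; columns `gene_name`, `feature_type`, `strand`, `start`, `end`,
#' and optional `trans_spliced`, `copy_index`, `partial`). Coordinates in
#' both dialects are 1-based inclusive and kept that way internally.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"feature_table"`.
#' @param genome_id Identifier to attach; defaults to the file's seqid
#'   (gff3) or the file name.
#' @param genome_length Optional genome length in bp used for bounds
#'   checking.
#' @param circular Logical; on circular genomes an exon may run past
#'   `genome_length` to represent an origin-spanning feature.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, dialect = c("gff3", "feature_table"),
                             genome_id = NULL, genome_length = NULL,
                             circular = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- switch(dialect,
    gff3 = parse_gff3(path),
    feature_table = parse_feature_table(path)
  )
  if (is.null(genome_id)) {
    genome_id <- if (!is.null(tab$seqid) && length(unique(tab$seqid)) == 1L) {
      tab$seqid[1]
    } else {
      tools::file_path_sans_ext(basename(path))
    }
  }
  if (!all(tab$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in ", path, ": ",
         paste(setdiff(unique(tab$strand), c("+", "-")), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(genome_length)) {
    lim <- if (circular) 2L * genome_length else genome_length
    if (any(tab$start < 1L) || any(tab$end > lim)) {
      stop("exon outside genome bounds (length ", genome_length, ") in ",
           path, call. = FALSE)
    }
  }
  key <- paste0(tab$gene_name, "#", tab$copy_index)
  feats <- lapply(split(tab, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    gene_feature(
      gene_name = d$gene_name[1], feature_type = d$feature_type[1],
      strand = d$strand[1], exons = cbind(d$start, d$end),
      trans_spliced = d$trans_spliced[1], copy_index = d$copy_index[1],
      partial = d$partial[1]
    )
  })
  names(feats) <- NULL
  annotation_set(genome_id, feats)
}

## Minimal GFF3 reader for the dialect this package writes: gene rows carry
## ID and gene= attributes, exon segments (CDS/tRNA/rRNA rows) point at them
## via Parent=. Returns one row per exon segment.
parse_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("empty GFF3 file: ", path, call. = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) {
    stop("malformed GFF3 (expected 9 tab-separated columns): ", path,
         call. = FALSE)
  }
  f <- do.call(rbind, f)
  type <- f[, 3]
  seg <- f[type %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  if (nrow(seg) == 0L) stop("no CDS/tRNA/rRNA rows in ", path, call. = FALSE)
  attrs <- seg[, 9]
  get1 <- function(key) {
    vapply(attrs, function(a) {
      m <- regmatches(a, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), a,
                                 perl = TRUE))
      if (length(m) == 0L) NA_character_ else sub(paste0("^;?", key, "="), "", m)
    }, character(1), USE.NAMES = FALSE)
  }
  parent <- get1("Parent")
  id <- get1("ID")
  gene <- get1("gene")
  copy <- suppressWarnings(as.integer(get1("copy_index")))
  ts <- tolower(get1("trans_spliced")) %in% "true"
  partial <- tolower(get1("partial")) %in% "true"
  group <- ifelse(is.na(parent), ifelse(is.na(id), gene, id), parent)
  gene_name <- ifelse(is.na(gene), sub("^(gene|cds)[-:]", "", group), gene)
  data.frame(
    seqid = seg[, 1], feature_type = seg[, 3],
    start = as.integer(seg[, 4]), end = as.integer(seg[, 5]),
    strand = seg[, 7], gene_name = gene_name,
    copy_index = ifelse(is.na(copy), 1L, copy),
    trans_spliced = ts, partial = partial,
    stringsAsFactors = FALSE
  )
}

parse_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_name", "feature_type", "strand", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tab$copy_index)) tab$copy_index <- 1L
  if (is.null(tab$trans_spliced)) tab$trans_spliced <- FALSE
  if (is.null(tab$partial)) tab$partial <- FALSE
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab
}

#' Write an annotation set as GFF3
#'
#' Writes one `gene` row per feature plus one row per exon segment
#' (type = feature type) linked by `Parent`. Coordinates are 1-based
#' inclusive. [read_annotations()] round-trips this output exactly.
#'
#' @param annot An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annot, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (f in annot$features) {
    gid <- sprintf("gene-%s.%d", f$gene_name, f$copy_index)
    span <- c(min(f$exons[, "start"]), max(f$exons[, "end"]))
    writeLines(paste(annot$genome_id, "plastcompare", "gene",
                     span[1], span[2], ".", f$strand, ".",
                     sprintf("ID=%s;gene=%s;copy_index=%d", gid, f$gene_name,
                             f$copy_index), sep = "\t"), con)
    for (i in seq_len(nrow(f$exons))) {
      extra <- paste0(
        if (f$trans_spliced) ";trans_spliced=true" else "",
        if (f$partial) ";partial=true" else ""
      )
      writeLines(paste(annot$genome_id, "plastcompare", f$feature_type,
                       f$exons[i, "start"], f$exons[i, "end"], ".",
                       f$strand, if (f$feature_type == "CDS") "0" else ".",
                       sprintf("ID=%s-seg%d;Parent=%s;gene=%s;copy_index=%d%s",
                               gid, i, gid, f$gene_name, f$copy_index, extra),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

## Extract the genomic substring for one exon, wrapping the origin of a
## circular genome when end > length.
exon_sequence <- function(genome, start, end) {
  n <- genome$length
  if (end <= n) return(substr(genome$sequence, start, end))
  if (!genome$circular) {
    stop("exon ", start, "..", end, " beyond the end of linear genome ",
         genome$id, call. = FALSE)
  }
  paste0(substr(genome$sequence, start, n),
         substr(genome$sequence, 1L, end - n))
}

#' Extract spliced coding sequences
#'
#' Concatenates each CDS feature's exons in translation order
#' (reverse-complementing minus-strand features), resolving origin-spanning
#' exons of circular genomes by wrap-around.
#'
#' @param genome A [genome_record()].
#' @param annot An [annotation_set()] for that genome.
#' @param skip_trans_spliced Drop features flagged `trans_spliced` (the
#'   rps12 situation) instead of splicing them.
#' @return Named character vector of coding sequences; names are
#'   `gene_name` for unique genes and `gene_name.copy_index` for
#'   IR-duplicated copies.
#' @examples
#' g <- genome_record("toy", "ATGAAATAA", circular = FALSE)
#' a <- annotation_set("toy", list(
#'   gene_feature("demo", "CDS", "+", cbind(1, 9))))
#' extract_cds(g, a)
#' @export
extract_cds <- function(genome, annot, skip_trans_spliced = TRUE) {
  cds <- Filter(function(f) f$feature_type == "CDS", annot$features)
  if (skip_trans_spliced) cds <- Filter(function(f) !f$trans_spliced, cds)
  out <- character(0)
  for (f in cds) {
    parts <- vapply(seq_len(nrow(f$exons)), function(i) {
      exon_sequence(genome, f$exons[i, "start"], f$exons[i, "end"])
    }, character(1))
    s <- paste(parts, collapse = "")
    if (f$strand == "-") s <- revcomp(s)
    if (nchar(s) %% 3L != 0L && !f$partial) {
      stop("CDS length of gene ", f$gene_name, " (copy ", f$copy_index,
           ") is ", nchar(s), " bp, not a multiple of 3", call. = FALSE)
    }
    nm <- if (f$copy_index == 1L) f$gene_name else {
      paste0(f$gene_name, ".", f$copy_index)
    }
    out[nm] <- s
  }
  out
}
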