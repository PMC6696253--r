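## SNP calling within aligned coding sequences, with codon context and
## transition/transversion + synonymous/nonsynonymous classification.

#' Classify a single-base substitution
#'
#' A<->G and C<->T are transitions (purine-purine / pyrimidine-pyrimidine);
#' every other pair is a transversion.
#'
#' @param ref_base,alt_base Differing bases in `{A, C, G, T}`.
#' @return List with `substitution_class` (`"transition"`/`"transversion"`)
#'   and `ts_subtype` (`"A<->G"`, `"C<->T"`, or `"none"`).
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (!ref_base %in% ACGT || !alt_base %in% ACGT) {
    stop("bases must be one of A, C, G, T", call. = FALSE)
  }
  if (ref_base == alt_base) {
    stop("ref and alt base are identical; not a substitution", call. = FALSE)
  }
  pair <- paste(sort(c(ref_base, alt_base)), collapse = "")
  if (pair == "AG") {
    list(substitution_class = "transition", ts_subtype = "A<->G")
  } else if (pair == "CT") {
    list(substitution_class = "transition", ts_subtype = "C<->T")
  } else {
    list(substitution_class = "transversion", ts_subtype = "none")
  }
}

#' Coding effect of a codon change
#'
#' Synonymous if and only if both codons translate to the same amino acid
#' (plastid/bacterial code, table 11, whose codon-to-amino-acid assignments
#' equal the standard code).
#'
#' @param ref_codon,alt_codon Trinucleotides over `{A, C, G, T}`.
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
coding_effect <- function(ref_codon, alt_codon) {
  ref_codon <- toupper(ref_codon); alt_codon <- toupper(alt_codon)
  if (grepl("[^ACGT]", ref_codon) || grepl("[^ACGT]", alt_codon) ||
      nchar(ref_codon) != 3L || nchar(alt_codon) != 3L) {
    stop("codons must be trinucleotides over A, C, G, T", call. = FALSE)
  }
  gc <- codon_table()
  if (gc[[ref_codon]] == gc[[alt_codon]]) "synonymous" else "nonsynonymous"
}

## SNP records for one aligned gene pair. Positions are 1-based on genome
## A's spliced, strand-corrected coding sequence. Mismatches adjacent to or
## inside gap runs are not called (warned). Multi-base codon changes yield
## one record per changed base, all sharing the codon's amino-acid change.
snps_for_gene <- function(columns, gene_name, copy_index = 1L) {
  gc <- codon_table()
  a <- columns$a; b <- columns$b
  empty <- data.frame(
    gene_name = character(0), copy_index = integer(0),
    gene_position = integer(0), codon_index = integer(0),
    codon_position = integer(0), ref_base = character(0),
    alt_base = character(0), ref_codon = character(0),
    alt_codon = character(0), ref_aa = character(0), alt_aa = character(0),
    substitution_class = character(0), ts_subtype = character(0),
    coding_effect = character(0)
  )
  gap <- a == "-" | b == "-"
  near_gap <- gap
  if (any(gap)) {
    near_gap <- gap | c(gap[-1], FALSE) | c(FALSE, gap[-length(gap)])
  }
  mm <- a %in% ACGT & b %in% ACGT & a != b
  skipped <- mm & near_gap
  if (any(skipped)) {
    warning(sum(skipped), " mismatch(es) adjacent to a gap run in gene ",
            gene_name, " skipped", call. = FALSE)
  }
  mm <- mm & !near_gap
  if (!any(mm)) return(empty)
  apos <- cumsum(a != "-")
  rows <- list()
  for (i in which(mm)) {
    p <- apos[i]
    ci <- (p - 1L) %/% 3L + 1L
    cp <- (p - 1L) %% 3L + 1L
    # codon columns: the three columns holding A positions of codon ci
    cidx <- which(apos %in% ((ci - 1L) * 3L + 1:3) & a != "-")
    if (length(cidx) != 3L || any(a[cidx] == "-") || any(b[cidx] == "-") ||
        any(!b[cidx] %in% ACGT)) {
      warning("codon ", ci, " of gene ", gene_name,
              " not cleanly aligned; mismatch skipped", call. = FALSE)
      next
    }
    ref_codon <- paste(a[cidx], collapse = "")
    alt_codon <- paste(b[cidx], collapse = "")
    cls <- classify_substitution(a[i], b[i])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_name = gene_name, copy_index = copy_index,
      gene_position = p, codon_index = ci, codon_position = cp,
      ref_base = a[i], alt_base = b[i],
      ref_codon = ref_codon, alt_codon = alt_codon,
      ref_aa = gc[[ref_codon]], alt_aa = gc[[alt_codon]],
      substitution_class = cls$substitution_class,
      ts_subtype = cls$ts_subtype,
      coding_effect = if (gc[[ref_codon]] == gc[[alt_codon]]) {
        "synonymous"
      } else "nonsynonymous"
    )
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Call coding SNPs between two annotated genomes
#'
#' Extracts the spliced coding sequence of every shared CDS (per copy),
#' aligns each pair globally, and emits one record per mismatching gap-free
#' column. Positions are 1-based on genome A's spliced coding sequence;
#' IR-duplicated genes yield records per copy. Multi-base codon changes are
#' recorded as one record per changed base, each inheriting the whole-codon
#' amino-acid comparison.
#'
#' @param genome_a,genome_b [genome_record()]s.
#' @param annot_a,annot_b Matching [annotation_set()]s.
#' @param skip_trans_spliced Passed to [extract_cds()].
#' @return data.frame of SNP records (zero rows if the genomes' coding
#'   sequences are identical).
#' @export
call_snps <- function(genome_a, genome_b, annot_a, annot_b,
                      skip_trans_spliced = TRUE) {
  cds_a <- extract_cds(genome_a, annot_a, skip_trans_spliced)
  cds_b <- extract_cds(genome_b, annot_b, skip_trans_spliced)
  shared <- intersect(names(cds_a), names(cds_b))
  out <- list()
  for (nm in shared) {
    if (identical(cds_a[[nm]], cds_b[[nm]])) next
    cols <- align_gene_pair(cds_a[[nm]], cds_b[[nm]])
    gene <- sub("\\.\\d+$", "", nm)
    copy <- if (grepl("\\.\\d+$", nm)) {
      as.integer(sub("^.*\\.", "", nm))
    } else 1L
    out[[length(out) + 1L]] <- snps_for_gene(cols, gene, copy)
  }
  if (length(out) == 0L) {
    return(snps_for_gene(list(a = "A", b = "A"), "none")[0, ])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## greatest common divisor, for the reduced Ts:Tv ratio
gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)

#' Summarize SNP records
#'
#' Per-class totals, transition subtypes, coding effects, multi-hit codons
#' (codons hit by more than one record), codons carrying both a transition
#' and a transversion, and the reduced Ts:Tv ratio.
#'
#' @param records data.frame from [call_snps()] (or compatible).
#' @return List of counts; `ts_tv_ratio` is a string like `"1:1"` (or `NA`
#'   when either class is absent).
#' @export
summarize_snps <- function(records) {
  n <- nrow(records)
  ts <- sum(records$substitution_class == "transition")
  tv <- sum(records$substitution_class == "transversion")
  key <- if (n) {
    paste(records$gene_name, records$copy_index, records$codon_index)
  } else character(0)
  both <- 0L
  multi <- 0L
  if (n) {
    per <- split(records$substitution_class, key)
    both <- sum(vapply(per, function(k) {
      any(k == "transition") && any(k == "transversion")
    }, logical(1)))
    multi <- sum(vapply(per, length, integer(1)) > 1L)
  }
  ratio <- if (ts > 0L && tv > 0L) {
    g <- gcd(ts, tv)
    paste0(ts / g, ":", tv / g)
  } else NA_character_
  list(
    n = n, transitions = ts, transversions = tv,
    ts_AG = sum(records$ts_subtype == "A<->G"),
    ts_CT = sum(records$ts_subtype == "C<->T"),
    synonymous = sum(records$coding_effect == "synonymous"),
    nonsynonymous = sum(records$coding_effect == "nonsynonymous"),
    multi_hit_codons = multi, both_substitution_codons = both,
    ts_tv_ratio = ratio
  )
}
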