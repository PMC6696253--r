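## Codon counting, RSCU and amino-acid frequencies with plastome family
## conventions: the first codon of every CDS is assigned to a three-codon
## methionine family {AUG, AUA*, GUG*} (plastid alternative starts recoded
## to Met), stop codons form a terminator family and are included in the
## codon total.

ALL_CODONS <- {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

dna_to_rna <- function(x) chartr("T", "U", x)
rna_to_dna <- function(x) chartr("U", "T", x)

## round half up (paper-style display rounding)
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Count codons over a set of coding sequences
#'
#' Codons are counted in frame. The first codon of every CDS is recorded
#' separately (`start_counts`) and later assigned to the methionine family
#' whatever its identity, matching the plastid convention that alternative
#' starts (AUA, GUG) are read as Met. Stop codons are counted like any
#' other codon and included in `total_codons`.
#'
#' @param cds_list Named character vector or list of coding sequences
#'   (each a multiple of 3 in length).
#' @return An object of class `codon_count_table` with `counts` (named
#'   over the 64 DNA codons; non-initial codons), `start_counts` (initial
#'   codons), `total_codons` and `n_cds`.
#' @export
count_codons <- function(cds_list) {
  counts <- stats::setNames(integer(64), ALL_CODONS)
  starts <- stats::setNames(integer(64), ALL_CODONS)
  nms <- names(cds_list)
  for (i in seq_along(cds_list)) {
    s <- toupper(cds_list[[i]])
    if (nchar(s) == 0L) next
    if (nchar(s) %% 3L != 0L) {
      stop("CDS ", if (!is.null(nms)) nms[i] else i, " has length ",
           nchar(s), ", not a multiple of 3", call. = FALSE)
    }
    st <- seq(1L, nchar(s), by = 3L)
    cods <- substring(s, st, st + 2L)
    if (any(grepl("[^ACGT]", cods))) {
      stop("CDS ", if (!is.null(nms)) nms[i] else i,
           " contains ambiguous codons", call. = FALSE)
    }
    starts[cods[1L]] <- starts[cods[1L]] + 1L
    if (length(cods) > 1L) {
      tb <- table(cods[-1L])
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
  }
  structure(
    list(counts = counts, start_counts = starts,
         total_codons = sum(counts) + sum(starts),
         n_cds = length(cds_list)),
    class = "codon_count_table"
  )
}

#' Build a codon count table from a published-style codon usage listing
#'
#' Accepts a data.frame with columns `aa` (one-letter symbol, `*` for the
#' terminator) `codon` (RNA or DNA alphabet) and `count`, as printed in
#' codon-usage tables where AUA and GUG appear both under their standard
#' amino acid and, starred, under Met. Rows assigned to Met for codons
#' other than AUG are taken to be recoded start codons.
#'
#' @param df data.frame with columns `aa`, `codon`, `count`.
#' @return A `codon_count_table`.
#' @export
as_codon_count_table <- function(df) {
  stopifnot(all(c("aa", "codon", "count") %in% names(df)))
  counts <- stats::setNames(integer(64), ALL_CODONS)
  starts <- stats::setNames(integer(64), ALL_CODONS)
  gc <- codon_table()
  for (i in seq_len(nrow(df))) {
    cod <- rna_to_dna(toupper(df$codon[i]))
    cnt <- as.integer(df$count[i])
    if (df$aa[i] == "M" && gc[[cod]] != "M") {
      starts[cod] <- starts[cod] + cnt
    } else {
      counts[cod] <- counts[cod] + cnt
    }
  }
  structure(
    list(counts = counts, start_counts = starts,
         total_codons = sum(counts) + sum(starts), n_cds = NA_integer_),
    class = "codon_count_table"
  )
}

#' @export
print.codon_count_table <- function(x, ...) {
  cat(sprintf("<codon_count_table> %s codons over %s CDS (%d recoded starts)\n",
              format(x$total_codons, big.mark = ","),
              ifelse(is.na(x$n_cds), "?", x$n_cds),
              sum(x$start_counts[setdiff(ALL_CODONS, "ATG")])))
  invisible(x)
}

## family partition: standard one-letter families from the genetic code,
## except Met = {ATG, ATA*, GTG*} (plus any other recoded start) and the
## terminator family {TAA, TAG, TGA}
codon_families <- function(table) {
  gc <- codon_table()
  fam <- split(names(gc), unname(gc))        # includes "*" and "M" = ATG
  extra_starts <- names(which(table$start_counts > 0L))
  met <- union(c("ATG", "ATA", "GTG"), extra_starts)
  fam[["M"]] <- met
  fam
}

#' Relative synonymous codon usage
#'
#' For each codon, `RSCU = count / (family total / family size)`: observed
#' use relative to uniform use within its synonymous family. Families are
#' the standard amino-acid families plus a three-codon Met family
#' `{AUG, AUA*, GUG*}` (starred codons are recoded starts) and the
#' terminator family `{UAA, UAG, UGA}`. Codons of zero-total families get
#' `NA`.
#'
#' @param table A `codon_count_table`.
#' @return data.frame with `aa`, `codon` (RNA alphabet), `start_recode`,
#'   `count`, `rscu` (unrounded) and `rscu_display` (half-up, 3 decimals).
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_count_table"))
  fams <- codon_families(table)
  rows <- list()
  for (aa in sort(names(fams))) {
    cods <- sort(fams[[aa]])
    if (aa == "M") {
      cnt <- ifelse(cods == "ATG",
                    table$counts["ATG"] + table$start_counts["ATG"],
                    table$start_counts[cods])
      recode <- cods != "ATG"
    } else {
      cnt <- table$counts[cods]
      recode <- rep(FALSE, length(cods))
    }
    tot <- sum(cnt)
    size <- length(cods)
    val <- if (tot > 0L) cnt / (tot / size) else rep(NA_real_, size)
    rows[[length(rows) + 1L]] <- data.frame(
      aa = aa, codon = dna_to_rna(cods), start_recode = recode,
      count = as.integer(cnt), rscu = unname(val),
      rscu_display = unname(round_half_up(val, 3))
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Amino-acid usage frequencies
#'
#' Family totals as percentages of all codons (stop codons included in the
#' denominator). The display column uses four significant digits, the
#' precision codon-usage tables are customarily printed at.
#'
#' @param table A `codon_count_table` with `total_codons > 0`.
#' @return data.frame with `aa`, `count`, `percent` (unrounded) and
#'   `percent_display`.
#' @export
aa_frequencies <- function(table) {
  stopifnot(inherits(table, "codon_count_table"))
  if (table$total_codons <= 0L) {
    stop("empty codon table: no frequencies to compute", call. = FALSE)
  }
  fams <- codon_families(table)
  aa <- sort(names(fams))
  cnt <- vapply(aa, function(a) {
    cods <- fams[[a]]
    if (a == "M") {
      sum(table$counts["ATG"], table$start_counts[cods])
    } else {
      sum(table$counts[cods])
    }
  }, numeric(1))
  pct <- 100 * cnt / table$total_codons
  data.frame(aa = aa, count = as.integer(cnt), percent = unname(pct),
             percent_display = unname(signif(pct, 4)))
}
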