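## Quadripartite structure: detect the inverted-repeat pair, derive the
## LSC/IRb/SSC/IRa partition and the four junctions, and report boundary
## gene contraction/expansion.

#' Construct a quadripartite partition
#'
#' Intervals are 1-based inclusive; an interval whose `end` exceeds the
#' genome length wraps the circular origin. Junctions are the first base of
#' the downstream region in the order LSC, IRb, SSC, IRa.
#'
#' @param lsc,irb,ssc,ira Length-2 integer vectors `(start, end)`.
#' @param genome_length Total genome length in bp.
#' @return Object of class `quadripartite_partition` with the four
#'   intervals, `junctions` (named `JLB`, `JSB`, `JSA`, `JLA`),
#'   `region_lengths` and `genome_length`.
#' @export
quadripartite_partition <- function(lsc, irb, ssc, ira, genome_length) {
  ival_len <- function(x) x[2] - x[1] + 1L
  lens <- c(lsc = ival_len(lsc), irb = ival_len(irb),
            ssc = ival_len(ssc), ira = ival_len(ira))
  if (sum(lens) != genome_length) {
    stop("partition intervals do not tile the genome (",
         sum(lens), " != ", genome_length, ")", call. = FALSE)
  }
  if (lens["irb"] != lens["ira"]) {
    stop("IRa and IRb lengths differ", call. = FALSE)
  }
  wrap1 <- function(p) ((p - 1L) %% genome_length) + 1L
  structure(
    list(lsc = as.integer(lsc), irb = as.integer(irb),
         ssc = as.integer(ssc), ira = as.integer(ira),
         junctions = c(JLB = wrap1(irb[1]), JSB = wrap1(ssc[1]),
                       JSA = wrap1(ira[1]), JLA = wrap1(lsc[1])),
         region_lengths = lens, genome_length = as.integer(genome_length)),
    class = "quadripartite_partition"
  )
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat("<quadripartite_partition>", format(x$genome_length, big.mark = ","),
      "bp\n")
  for (r in c("lsc", "irb", "ssc", "ira")) {
    cat(sprintf("  %s: %s..%s (%s bp)\n", toupper(r),
                format(x[[r]][1], big.mark = ","),
                format(x[[r]][2], big.mark = ","),
                format(x$region_lengths[r], big.mark = ",")))
  }
  invisible(x)
}

## maximal exact inverted-repeat pairs of a linear string via shared unique
## k-mers between S and revcomp(S); returns candidates as rows
## (start1, end1, start2, end2, length)
ir_candidates_linear <- function(s, k) {
  n <- nchar(s)
  if (n < 2L * k) return(NULL)
  r <- revcomp(s)
  ks <- substring(s, 1:(n - k + 1L), k:n)
  kr <- substring(r, 1:(n - k + 1L), k:n)
  us <- !(duplicated(ks) | duplicated(ks, fromLast = TRUE))
  ur <- !(duplicated(kr) | duplicated(kr, fromLast = TRUE))
  common <- intersect(ks[us], kr[ur])
  if (length(common) == 0L) return(NULL)
  pi_ <- match(common, ks)
  pr <- match(common, kr)
  d <- pr - pi_
  o <- order(d, pi_)
  pi_ <- pi_[o]; pr <- pr[o]; d <- d[o]
  runbreak <- c(TRUE, !(d[-1L] == d[-length(d)] &
                          pi_[-1L] == pi_[-length(pi_)] + 1L))
  rid <- cumsum(runbreak)
  i1 <- tapply(pi_, rid, min); i2 <- tapply(pi_, rid, max) + k - 1L
  p1 <- tapply(pr, rid, min); p2 <- tapply(pr, rid, max) + k - 1L
  # map the revcomp interval back onto S
  j1 <- n - p2 + 1L; j2 <- n - p1 + 1L
  cand <- data.frame(start1 = as.integer(pmin(i1, j1)),
                     end1 = as.integer(pmin(i2, j2)),
                     start2 = as.integer(pmax(i1, j1)),
                     end2 = as.integer(pmax(i2, j2)))
  # each IR pair is reported from both arms; dedupe and drop self-overlaps
  cand <- unique(cand)
  cand <- cand[cand$end1 < cand$start2, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (q in seq_len(nrow(cand))) {
    # extend left of arm 1 together with right of arm 2
    while (cand$start1[q] > 1L && cand$end2[q] < n &&
           isTRUE(sv[cand$start1[q] - 1L] ==
                    unname(comp[sv[cand$end2[q] + 1L]]))) {
      cand$start1[q] <- cand$start1[q] - 1L
      cand$end2[q] <- cand$end2[q] + 1L
    }
    # extend right of arm 1 with left of arm 2, keeping the arms disjoint
    while (cand$end1[q] + 1L < cand$start2[q] - 1L &&
           isTRUE(sv[cand$end1[q] + 1L] ==
                    unname(comp[sv[cand$start2[q] - 1L]]))) {
      cand$end1[q] <- cand$end1[q] + 1L
      cand$start2[q] <- cand$start2[q] - 1L
    }
  }
  cand$length <- cand$end1 - cand$start1 + 1L
  cand[cand$length == cand$end2 - cand$start2 + 1L, , drop = FALSE]
}

#' Detect the inverted-repeat pair and quadripartite partition
#'
#' Finds the longest pair of disjoint segments where one is the exact
#' reverse complement of the other (seeded by shared unique k-mers between
#' the genome and its reverse complement, extended maximally). The longer
#' inter-IR segment is the LSC, the shorter the SSC; the IR downstream of
#' the LSC is IRb. Circularity is handled by retrying on a half-rotated
#' copy, so an IR spanning the origin is still found.
#'
#' @param genome A [genome_record()] (circular) or nucleotide string.
#' @param min_len Minimum IR length in bp (default 1000); shorter repeats
#'   raise a structure error.
#' @param k Seed k-mer length.
#' @return A [quadripartite_partition()].
#' @export
find_inverted_repeats <- function(genome, min_len = 1000L, k = 24L) {
  s <- if (inherits(genome, "genome_record")) genome$sequence else
    toupper(genome)
  n <- nchar(s)
  shift <- n %/% 2L
  rot <- paste0(substr(s, shift + 1L, n), substr(s, 1L, shift))
  best <- NULL; best_shift <- 0L
  for (sh in c(0L, shift)) {
    cand <- ir_candidates_linear(if (sh == 0L) s else rot, k)
    if (!is.null(cand) && nrow(cand)) {
      top <- cand[which.max(cand$length), ]
      if (is.null(best) || top$length > best$length) {
        best <- top; best_shift <- sh
      }
    }
  }
  if (is.null(best) || best$length < min_len) {
    stop("no inverted repeat of at least ", min_len,
         " bp found: not a quadripartite plastome", call. = FALSE)
  }
  un <- function(p) ((p + best_shift - 1L) %% n) + 1L   # unrotate
  ir1 <- c(best$start1, best$end1)
  ir2 <- c(best$start2, best$end2)
  inner <- c(best$end1 + 1L, best$start2 - 1L)
  outer_len <- n - best$length * 2L - (inner[2] - inner[1] + 1L)
  outer <- c(best$end2 + 1L, best$end2 + outer_len)   # wraps in rotated frame
  inner_len <- inner[2] - inner[1] + 1L
  if (inner_len >= outer_len) {   # inner segment is the LSC
    lsc <- inner; ssc <- outer
    irb <- ir2; ira <- ir1        # LSC is followed by ir2
  } else {
    lsc <- outer; ssc <- inner
    irb <- ir1; ira <- ir2
  }
  fix <- function(iv) {
    st <- un(iv[1])
    c(st, st + (iv[2] - iv[1]))
  }
  quadripartite_partition(fix(lsc), fix(irb), fix(ssc), fix(ira), n)
}

## circular helpers (1-based positions on a genome of length n)
circ_covers <- function(gs, len, p, n) ((p - gs) %% n) < len

#' Gene offsets at the four IR junctions
#'
#' For each junction, genes lying within `flank` bp are reported. A gene
#' overlapping the junction is an expansion: it reports the bp falling on
#' each side. A gene falling short of the junction is a contraction: it
#' reports the gap in bp between the gene boundary and the junction.
#'
#' @param partition A [quadripartite_partition()].
#' @param annot An [annotation_set()].
#' @param flank Reporting distance in bp (default 1000).
#' @return data.frame with `junction`, `gene_name`, `copy_index`, `strand`,
#'   `gene_start`, `gene_end`, `region` (region holding the gene, or the
#'   upstream region for spanning genes), `spans_junction`, `distance`
#'   (0 when spanning), `bp_upstream`, `bp_downstream` (bp on each side of
#'   the junction for spanning genes, `NA` otherwise).
#' @export
junction_offsets <- function(partition, annot, flank = 1000L) {
  n <- partition$genome_length
  region_of <- function(p) {
    for (r in c("lsc", "irb", "ssc", "ira")) {
      iv <- partition[[r]]
      if (circ_covers(iv[1], iv[2] - iv[1] + 1L, ((p - 1L) %% n) + 1L, n)) {
        return(toupper(r))
      }
    }
    NA_character_
  }
  rows <- list()
  for (jn in names(partition$junctions)) {
    J <- partition$junctions[[jn]]
    for (f in annot$features) {
      gs <- min(f$exons[, "start"]); ge <- max(f$exons[, "end"])
      len <- ge - gs + 1L
      spans <- circ_covers(gs, len, ((J - 2L) %% n) + 1L, n) &&
        circ_covers(gs, len, J, n)
      if (spans) {
        bp_down <- ((ge - J) %% n) + 1L
        bp_up <- len - bp_down
        dist <- 0L
      } else {
        gap_up <- (J - 1L - ge) %% n    # gene upstream of junction
        gap_down <- (gs - J) %% n       # gene downstream of junction
        dist <- min(gap_up, gap_down)
        bp_up <- NA_integer_; bp_down <- NA_integer_
      }
      if (dist > flank) next
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, gene_name = f$gene_name, copy_index = f$copy_index,
        strand = f$strand, gene_start = gs, gene_end = ge,
        region = region_of(gs), spans_junction = spans,
        distance = as.integer(dist), bp_upstream = bp_up,
        bp_downstream = bp_down
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(junction = character(0), gene_name = character(0),
                      copy_index = integer(0), strand = character(0),
                      gene_start = integer(0), gene_end = integer(0),
                      region = character(0), spans_junction = logical(0),
                      distance = integer(0), bp_upstream = integer(0),
                      bp_downstream = integer(0)))
  }
  res <- do.call(rbind, rows)
  res[order(match(res$junction, c("JLB", "JSB", "JSA", "JLA")),
            res$distance), , drop = FALSE]
}
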