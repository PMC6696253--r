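## Pairwise alignment: a banded global (Needleman-Wunsch) aligner for short
## segments and genes, and an anchor-and-chain aligner for whole plastomes.
## Default scores: match +1, mismatch -1, gap -2, linear gap cost; columns
## containing N score 0 (mismatch-neutral).

score_pair <- function(x, y, match = 1, mismatch = -1) {
  ifelse(x == "N" | y == "N", 0, ifelse(x == y, match, mismatch))
}

#' Banded global alignment of two nucleotide strings
#'
#' Needleman-Wunsch with linear gap cost restricted to a diagonal band. The
#' band is automatically widened to contain the main diagonal shift implied
#' by the length difference. Traceback prefers diagonal moves, so
#' equal-length high-identity pairs align gap-free.
#'
#' @param a,b Nucleotide strings.
#' @param match,mismatch,gap Scores (linear gap cost per gapped column).
#'   Columns with `N` score 0.
#' @param band Half-width of the band around the shifted main diagonal.
#' @return List with `a`, `b` (character vectors of aligned columns, `"-"`
#'   for gaps) and `score`.
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2, band = 64L) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0L && m == 0L) return(list(a = character(0), b = character(0),
                                      score = 0))
  if (n == 0L) return(list(a = rep("-", m), b = bv, score = gap * m))
  if (m == 0L) return(list(a = av, b = rep("-", n), score = gap * n))
  lo <- min(0L, m - n) - band
  hi <- max(0L, m - n) + band
  W <- hi - lo + 1L
  ds <- lo:hi
  M <- matrix(-Inf, nrow = n + 1L, ncol = W)
  d0 <- ds >= 0L & ds <= m
  M[1L, d0] <- gap * ds[d0]
  idx <- seq_len(W)
  for (i in seq_len(n)) {
    j <- i + ds
    valid <- j >= 0L & j <= m
    prev <- M[i, ]
    jj <- pmax(pmin(j, m), 1L)          # clamped index, masked below
    s <- score_pair(av[i], bv[jj], match, mismatch)
    diag_cand <- prev + ifelse(j >= 1L, s, -Inf)
    up_cand <- c(prev[-1L], -Inf) + gap
    cand <- pmax(diag_cand, up_cand)
    cand[!valid] <- -Inf
    # resolve within-row (gap-in-a) moves: r[c] = max_{c'<=c} cand[c'] + gap*(c-c')
    t <- cand - gap * idx
    r <- cummax(t) + gap * idx
    r[!valid] <- -Inf
    M[i + 1L, ] <- r
  }
  # traceback
  ai <- character(0); bi <- character(0)
  i <- n; j <- m; cpos <- (m - n) - lo + 1L
  while (i > 0L || j > 0L) {
    cur <- M[i + 1L, cpos]
    if (i > 0L && j > 0L &&
        M[i, cpos] + score_pair(av[i], bv[j], match, mismatch) == cur) {
      ai <- c(av[i], ai); bi <- c(bv[j], bi); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && cpos + 1L <= W && M[i, cpos + 1L] + gap == cur) {
      ai <- c(av[i], ai); bi <- c("-", bi); i <- i - 1L; cpos <- cpos + 1L
    } else if (j > 0L && cpos - 1L >= 1L && M[i + 1L, cpos - 1L] + gap == cur) {
      ai <- c("-", ai); bi <- c(bv[j], bi); j <- j - 1L; cpos <- cpos - 1L
    } else {
      stop("alignment traceback failed (band too narrow?)", call. = FALSE)
    }
  }
  list(a = ai, b = bi, score = M[n + 1L, (m - n) - lo + 1L])
}

#' Score an alignment column list
#'
#' The implied score of a set of aligned columns under the package's default
#' scoring: used to compare the anchor-and-chain alignment with a full
#' dynamic-programming alignment.
#'
#' @param columns List with character vectors `a` and `b`.
#' @param match,mismatch,gap Scores.
#' @return Numeric score.
#' @export
alignment_score <- function(columns, match = 1, mismatch = -1, gap = -2) {
  a <- columns$a; b <- columns$b
  g <- a == "-" | b == "-"
  sum(g) * gap + sum(score_pair(a[!g], b[!g], match, mismatch))
}

## longest strictly-increasing subsequence (patience algorithm) on v;
## returns indices of one LIS
lis_indices <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  tails_val <- numeric(0)
  tails_idx <- integer(0)
  prev <- integer(n)
  for (t in seq_len(n)) {
    p <- findInterval(v[t] - 0.5, tails_val)  # tails strictly below v[t]
    prev[t] <- if (p >= 1L) tails_idx[p] else 0L
    tails_val[p + 1L] <- v[t]
    tails_idx[p + 1L] <- t
  }
  out <- integer(0)
  t <- tails_idx[length(tails_idx)]
  while (t > 0L) { out <- c(t, out); t <- prev[t] }
  out
}

#' Anchor-and-chain alignment of two co-linear plastomes
#'
#' Unique shared k-mers anchor a monotone map between the two genomes; the
#' longest strictly-increasing anchor chain is kept, contiguous same-diagonal
#' anchors are merged into exact blocks, and inter-anchor segments are closed
#' by banded global alignment. Designed for the near-identical, co-linear
#' regime of conspecific or congeneric plastome pairs; a chain covering less
#' than half of either genome raises a co-linearity error (it suggests a
#' rearrangement this aligner does not model).
#'
#' @param seq_a,seq_b Nucleotide strings or [genome_record()]s.
#' @param k Anchor k-mer length; 21-mers are effectively unique at plastome
#'   scale.
#' @param band Band half-width for closing inter-anchor segments.
#' @param min_chain_cover Minimum fraction of each genome the anchor chain
#'   must span.
#' @return An object of class `alignment_map`: `blocks` (data.frame
#'   `start_a`, `start_b`, `length`; 1-based), `gaps` (data.frame `genome`
#'   -- the genome carrying the extra bases -- `start`, `end`, `length`),
#'   `columns` (aligned column vectors), `length_a`, `length_b`, `score`.
#' @export
anchor_align <- function(seq_a, seq_b, k = 21L, band = 64L,
                         min_chain_cover = 0.5) {
  if (inherits(seq_a, "genome_record")) seq_a <- seq_a$sequence
  if (inherits(seq_b, "genome_record")) seq_b <- seq_b$sequence
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (na < k || nb < k) stop("sequences shorter than anchor size k",
                             call. = FALSE)
  ka <- substring(seq_a, 1:(na - k + 1L), k:na)
  kb <- substring(seq_b, 1:(nb - k + 1L), k:nb)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  common <- intersect(ka[ua], kb[ub])
  if (length(common) == 0L) {
    stop("no shared unique anchors: sequences are not co-linear ",
         "(rearranged or reverse-complemented input?)", call. = FALSE)
  }
  pa <- match(common, ka)
  pb <- match(common, kb)
  o <- order(pa)
  pa <- pa[o]; pb <- pb[o]
  keep <- lis_indices(pb)
  pa <- pa[keep]; pb <- pb[keep]
  span_a <- pa[length(pa)] + k - 1L - pa[1L] + 1L
  span_b <- pb[length(pb)] + k - 1L - pb[1L] + 1L
  if (span_a < min_chain_cover * na || span_b < min_chain_cover * nb) {
    stop("anchor chain covers < ", round(100 * min_chain_cover),
         "% of a genome: sequences are not co-linear", call. = FALSE)
  }
  # merge contiguous same-diagonal anchors into exact blocks
  dg <- pb - pa
  newblk <- c(TRUE, !(dg[-1L] == dg[-length(dg)] &
                        pa[-1L] <= pa[-length(pa)] + k))
  bid <- cumsum(newblk)
  bs_a <- tapply(pa, bid, min)
  bs_b <- tapply(pb, bid, min)
  be_a <- tapply(pa, bid, max) + k - 1L
  blocks <- data.frame(start_a = as.integer(bs_a),
                       start_b = as.integer(bs_b),
                       length = as.integer(be_a - bs_a + 1L))
  av <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  bv <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  cols_a <- list(); cols_b <- list()
  ca <- 1L; cb <- 1L   # next unconsumed position in each genome
  for (r in seq_len(nrow(blocks))) {
    sa <- blocks$start_a[r]; sb <- blocks$start_b[r]; len <- blocks$length[r]
    if (sa > ca || sb > cb) {
      seg <- nw_align(substr(seq_a, ca, sa - 1L), substr(seq_b, cb, sb - 1L),
                      band = max(band, abs((sa - ca) - (sb - cb)) + 8L))
      cols_a[[length(cols_a) + 1L]] <- seg$a
      cols_b[[length(cols_b) + 1L]] <- seg$b
    }
    cols_a[[length(cols_a) + 1L]] <- av[sa:(sa + len - 1L)]
    cols_b[[length(cols_b) + 1L]] <- bv[sb:(sb + len - 1L)]
    ca <- sa + len; cb <- sb + len
  }
  if (ca <= na || cb <= nb) {
    seg <- nw_align(substr(seq_a, ca, na), substr(seq_b, cb, nb),
                    band = max(band, abs((na - ca) - (nb - cb)) + 8L))
    cols_a[[length(cols_a) + 1L]] <- seg$a
    cols_b[[length(cols_b) + 1L]] <- seg$b
  }
  columns <- list(a = unlist(cols_a), b = unlist(cols_b))
  structure(
    list(blocks = blocks, gaps = alignment_gaps(columns),
         columns = columns, length_a = na, length_b = nb,
         score = alignment_score(columns)),
    class = "alignment_map"
  )
}

## derive gap runs from aligned columns; `genome` names the genome that
## carries the extra bases (a gap in A's row means bases present only in B)
alignment_gaps <- function(columns) {
  a <- columns$a; b <- columns$b
  pos_a <- cumsum(a != "-")
  pos_b <- cumsum(b != "-")
  out <- list()
  for (side in c("a", "b")) {
    gapped <- if (side == "a") a == "-" else b == "-"
    pos <- if (side == "a") pos_b else pos_a
    r <- rle(gapped)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    if (length(w)) {
      out[[length(out) + 1L]] <- data.frame(
        genome = if (side == "a") "B" else "A",
        start = pos[starts[w]], end = pos[ends[w]],
        length = r$lengths[w]
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(genome = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf(
    "<alignment_map> %s x %s bp: %d exact blocks, %d gap runs, score %g\n",
    format(x$length_a, big.mark = ","), format(x$length_b, big.mark = ","),
    nrow(x$blocks), nrow(x$gaps), x$score))
  invisible(x)
}

#' Globally align one homologous gene pair
#'
#' Global alignment of two spliced coding sequences with the package's
#' default scores. In the low-divergence regime of congeneric plastomes,
#' equal-length CDS pairs align gap-free.
#'
#' @param cds_a,cds_b Coding nucleotide strings (non-empty).
#' @param band Band half-width.
#' @return List with aligned column vectors `a`, `b` and `score`.
#' @export
align_gene_pair <- function(cds_a, cds_b, band = 64L) {
  if (!nzchar(cds_a) || !nzchar(cds_b)) {
    stop("empty coding sequence", call. = FALSE)
  }
  nw_align(cds_a, cds_b, band = band)
}
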