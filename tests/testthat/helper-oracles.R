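# Independent oracles the implementation is checked against. Each oracle
# deliberately takes a different route than the package code: full
# dynamic programming via Biostrings for the anchor aligner, a per-site
# character loop for sliding Pi, seqinr's genetic code for NG86, and a
# backreference-regex scan for the SSR scanner.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Thue-Morse word: cube-free, so it contains no perfect tandem run of three
# or more repeats of any unit -- a background guaranteed free of SSRs under
# every preset used here
thue_morse_seq <- function(n, letters = c("C", "G")) {
  bits <- vapply(0:(n - 1L), function(i) {
    sum(as.integer(intToBits(i))) %% 2L
  }, integer(1))
  paste(letters[bits + 1L], collapse = "")
}

# full Needleman-Wunsch score under match +1 / mismatch -1 / gap -2
oracle_nw_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = 2,
                                scoreOnly = TRUE)
}

# naive per-site sliding Pi: explicit loops, no cumulative sums
oracle_sliding_pi <- function(colsA, colsB, window, step) {
  apos <- 0L
  pos_a <- integer(length(colsA))
  for (i in seq_along(colsA)) {
    if (colsA[i] != "-") apos <- apos + 1L
    pos_a[i] <- apos
  }
  len_a <- apos
  starts <- seq(1L, len_a, by = step)
  out <- data.frame(start = starts, end = pmin(starts + window - 1L, len_a),
                    valid_sites = NA_integer_, pi = NA_real_)
  bases <- c("A", "C", "G", "T")
  for (w in seq_along(starts)) {
    v <- 0L; d <- 0L
    for (i in seq_along(colsA)) {
      if (colsA[i] == "-") next
      if (pos_a[i] < out$start[w] || pos_a[i] > out$end[w]) next
      if (!(colsA[i] %in% bases) || !(colsB[i] %in% bases)) next
      v <- v + 1L
      if (colsA[i] != colsB[i]) d <- d + 1L
    }
    out$valid_sites[w] <- v
    out$pi[w] <- if (v > 0) d / v else NA_real_
  }
  out
}

# NG86 via seqinr's genetic code: independent site counting and pathway
# enumeration (explicit permutation lists, stop-free paths preferred)
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_ng86 <- function(codons_a, codons_b) {
  bases <- c("A", "C", "G", "T")
  syn_frac <- function(codon) {
    aa <- oracle_translate(codon)
    s <- 0
    for (p in 1:3) {
      for (alt in bases[bases != substr(codon, p, p)]) {
        mut <- codon
        substr(mut, p, p) <- alt
        if (oracle_translate(mut) != "*" && oracle_translate(mut) == aa) {
          s <- s + 1 / 3
        }
      }
    }
    s
  }
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (q in seq_along(codons_a)) {
    ca <- codons_a[q]; cb <- codons_b[q]
    S <- S + (syn_frac(ca) + syn_frac(cb)) / 2
    N <- N + 3 - (syn_frac(ca) + syn_frac(cb)) / 2
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(pos) == 0L) next
    paths <- perms_of(pos)
    res <- matrix(NA_real_, nrow = length(paths), ncol = 3)
    for (pi_ in seq_along(paths)) {
      cur <- ca; sd <- 0; nd <- 0; ok <- TRUE
      for (p in paths[[pi_]]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (oracle_translate(nxt) == "*" && nxt != cb) ok <- FALSE
        if (oracle_translate(nxt) == oracle_translate(cur)) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      res[pi_, ] <- c(sd, nd, ok)
    }
    use <- res[, 3] == 1
    if (!any(use)) use <- rep(TRUE, nrow(res))
    Sd <- Sd + mean(res[use, 1])
    Nd <- Nd + mean(res[use, 2])
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ps = if (S > 0) Sd / S else 0, pn = if (N > 0) Nd / N else 0)
}

# regex-based perfect-SSR scan: backreference matches per unit size, motif
# primitivity via the doubled-string rotation trick, then the same
# smallest-unit-first overlap resolution rule as the scanner's contract
oracle_find_ssrs <- function(s, thresholds) {
  cand <- list()
  for (u in 1:6) {
    minrep <- thresholds[u]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, minrep - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (i in seq_along(m)) {
      start <- m[i]
      len <- attr(m, "match.length")[i]
      motif <- substr(s, start, start + u - 1L)
      # primitive iff motif does not occur in (motif+motif) minus its ends
      doubled <- substr(paste0(motif, motif), 2L, 2L * u - 1L)
      if (u > 1L && grepl(motif, doubled, fixed = TRUE)) next
      reps <- len %/% u
      cand[[length(cand) + 1L]] <- data.frame(
        motif = motif, unit_size = u, repeats = reps, start = start,
        end = start + reps * u - 1L)
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(motif = character(0), unit_size = integer(0),
                      repeats = integer(0), start = integer(0),
                      end = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$unit_size, cand$start), , drop = FALSE]
  taken <- logical(nchar(s))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  res <- cand[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
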