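## Sliding-window nucleotide diversity, K2P distance, and Nei-Gojobori
## (1986) Ka/Ks with selection classification.

ACGT <- c("A", "C", "G", "T")

## accept an alignment_map, a list(a=, b=) of aligned column vectors, or two
## equal-length strings
as_columns <- function(x, y = NULL) {
  if (inherits(x, "alignment_map")) return(x$columns)
  if (is.list(x) && !is.null(x$a) && !is.null(x$b)) {
    return(list(a = x$a, b = x$b))
  }
  stopifnot(is.character(x), is.character(y))
  if (length(x) == 1L) x <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  if (length(y) == 1L) y <- strsplit(toupper(y), "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) {
    stop("sequences of unequal length; align them first", call. = FALSE)
  }
  list(a = x, b = y)
}

#' Sliding-window nucleotide diversity
#'
#' For two aligned sequences, nucleotide diversity (Pi) in a window reduces
#' to the per-window p-distance: differing valid columns over valid columns.
#' A column is valid when both sequences carry an unambiguous base (gap and
#' N columns are excluded from numerator and denominator alike). Windows
#' tile genome A's ungapped coordinates; the trailing partial windows are
#' retained and flagged.
#'
#' @param alignment An `alignment_map` or a list with aligned column vectors
#'   `a` and `b`.
#' @param window Window length in bp (default 600).
#' @param step Step size in bp (default 200).
#' @return data.frame with 1-based `start`, `end` (genome A coordinates),
#'   `valid_sites`, `differences`, `pi` (`NA` when a window has no valid
#'   site), and `partial`.
#' @export
sliding_pi <- function(alignment, window = 600L, step = 200L) {
  stopifnot(window >= step, step >= 1L)
  cols <- as_columns(alignment)
  a <- cols$a; b <- cols$b
  in_a <- a != "-"
  len_a <- sum(in_a)
  if (len_a == 0L) stop("alignment contains no genome-A bases", call. = FALSE)
  valid <- a %in% ACGT & b %in% ACGT
  diff <- valid & a != b
  # per-A-position indicator vectors
  vA <- integer(len_a); dA <- integer(len_a)
  apos <- cumsum(in_a)
  vA[apos[valid & in_a]] <- 1L
  dA[apos[diff & in_a]] <- 1L
  cv <- c(0L, cumsum(vA))
  cd <- c(0L, cumsum(dA))
  starts <- seq.int(1L, len_a, by = step)
  ends <- pmin(starts + window - 1L, len_a)
  vs <- cv[ends + 1L] - cv[starts]
  df <- cd[ends + 1L] - cd[starts]
  data.frame(
    start = starts, end = ends, valid_sites = vs, differences = df,
    pi = ifelse(vs > 0L, df / vs, NA_real_),
    partial = (starts + window - 1L) > len_a
  )
}

#' Call divergence hotspots on a Pi track
#'
#' Windows with Pi strictly greater than the threshold are flagged;
#' adjacent flagged windows are merged into regions and each region's
#' maximum Pi is reported.
#'
#' @param track A data.frame from [sliding_pi()].
#' @param threshold Strict lower bound (default 0.006).
#' @return data.frame with `region_start`, `region_end`, `n_windows`,
#'   `max_pi`; zero rows when nothing exceeds the threshold.
#' @export
detect_hotspots <- function(track, threshold = 0.006) {
  stopifnot(nrow(track) > 0L)
  hot <- !is.na(track$pi) & track$pi > threshold
  if (!any(hot)) {
    return(data.frame(region_start = integer(0), region_end = integer(0),
                      n_windows = integer(0), max_pi = numeric(0)))
  }
  r <- rle(hot)
  iend <- cumsum(r$lengths)
  istart <- iend - r$lengths + 1L
  w <- which(r$values)
  data.frame(
    region_start = track$start[istart[w]],
    region_end = track$end[iend[w]],
    n_windows = r$lengths[w],
    max_pi = vapply(w, function(i) {
      max(track$pi[istart[i]:iend[i]], na.rm = TRUE)
    }, numeric(1))
  )
}

#' Kimura two-parameter distance
#'
#' From gap-free unambiguous columns, the transition proportion
#' `P` (A<->G, C<->T) and transversion proportion `Q` give
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param x An alignment column list, or a nucleotide string with `y`.
#' @param y Optional second string (must be the same length as `x`).
#' @return List with `d`, `P`, `Q` and `valid_sites`.
#' @export
k2p_distance <- function(x, y = NULL) {
  cols <- as_columns(x, y)
  a <- cols$a; b <- cols$b
  valid <- a %in% ACGT & b %in% ACGT
  n <- sum(valid)
  if (n == 0L) stop("no valid (gap-free, unambiguous) columns", call. = FALSE)
  a <- a[valid]; b <- b[valid]
  diffs <- a != b
  pur <- c("A", "G")
  ts <- diffs & ((a %in% pur) == (b %in% pur))
  P <- sum(ts) / n
  Q <- sum(diffs & !ts) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    stop("sequences saturated: K2P distance undefined (P=", round(P, 4),
         ", Q=", round(Q, 4), ")", call. = FALSE)
  }
  d <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  list(d = d, P = P, Q = Q, valid_sites = n)
}

## ---- NG86 ------------------------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE  # plastid (table 11) codon->aa is identical
  stats::setNames(as.character(gc), names(gc))
}

translate_codon <- function(codon, gc = codon_table()) {
  aa <- unname(gc[codon])
  if (any(is.na(aa))) {
    stop("invalid codon: ", paste(codon[is.na(aa)], collapse = ", "),
         call. = FALSE)
  }
  aa
}

## fraction of synonymous sites in one codon (changes to stop codons count
## as nonsynonymous)
syn_sites_codon <- function(codon, gc = codon_table()) {
  aa <- gc[[codon]]
  bases <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (p in 1:3) {
    for (alt in setdiff(ACGT, bases[p])) {
      mut <- bases
      mut[p] <- alt
      mc <- paste(mut, collapse = "")
      if (gc[[mc]] != "*" && gc[[mc]] == aa) s <- s + 1 / 3
    }
  }
  s
}

## average synonymous/nonsynonymous step counts over all minimal
## substitution pathways between two codons; pathways through stop codons
## are discarded (all pathways are used if every one passes through a stop)
codon_path_diffs <- function(c1, c2, gc = codon_table()) {
  b1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  pos <- which(b1 != b2)
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd,
                  list(pos),
                  list(pos, pos[2:1]),
                  list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
                       pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)]))
  eval_path <- function(ord) {
    cur <- b1
    sd <- 0; nn <- 0; ok <- TRUE
    for (p in ord) {
      prev_aa <- gc[[paste(cur, collapse = "")]]
      cur[p] <- b2[p]
      cc <- paste(cur, collapse = "")
      aa <- gc[[cc]]
      if (aa == "*" && cc != c2) ok <- FALSE   # intermediate stop
      if (aa == prev_aa) sd <- sd + 1 else nn <- nn + 1
    }
    c(sd = sd, nd = nn, ok = as.numeric(ok))
  }
  res <- vapply(perms, eval_path, numeric(3))
  use <- res["ok", ] == 1
  if (!any(use)) use <- rep(TRUE, ncol(res))
  c(sd = mean(res["sd", use]), nd = mean(res["nd", use]))
}

#' Nei-Gojobori (1986) Ka and Ks
#'
#' Fractional synonymous/nonsynonymous site counts averaged over both
#' sequences; observed differences resolved by averaging over all minimal
#' substitution pathways per codon (pathways through stop codons are
#' discarded); Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)` applied to
#' the proportions pN and pS.
#'
#' @param cds_a,cds_b Aligned coding strings of equal length (multiple of
#'   3, gap-free), or a two-column character matrix of codon pairs.
#' @return List with `ka`, `ks`, `ka_ks` (`NA` when `ks` is 0), the site
#'   counts `N`, `S` and difference counts `Nd`, `Sd`, and `pn`, `ps`.
#' @export
ng86_kaks <- function(cds_a, cds_b = NULL) {
  cmp <- ng86_components(cds_a, cds_b)
  ps <- cmp$ps; pn <- cmp$pn
  if (1 - 4 * ps / 3 <= 0 || 1 - 4 * pn / 3 <= 0) {
    stop("substitution proportion saturated: Jukes-Cantor correction ",
         "undefined", call. = FALSE)
  }
  ks <- -0.75 * log(1 - 4 * ps / 3)
  ka <- -0.75 * log(1 - 4 * pn / 3)
  list(ka = ka, ks = ks, ka_ks = if (ks > 0) ka / ks else NA_real_,
       N = cmp$N, S = cmp$S, Nd = cmp$Nd, Sd = cmp$Sd, pn = pn, ps = ps)
}

## uncorrected NG86 site and difference counts (no Jukes-Cantor step)
ng86_components <- function(cds_a, cds_b = NULL) {
  gc <- codon_table()
  if (is.matrix(cds_a)) {
    codons_a <- cds_a[, 1]; codons_b <- cds_a[, 2]
  } else {
    stopifnot(nchar(cds_a) == nchar(cds_b), nchar(cds_a) %% 3 == 0,
              nchar(cds_a) > 0)
    st <- seq(1L, nchar(cds_a), by = 3L)
    codons_a <- substring(toupper(cds_a), st, st + 2L)
    codons_b <- substring(toupper(cds_b), st, st + 2L)
  }
  if (any(grepl("[^ACGT]", c(codons_a, codons_b)))) {
    stop("codons must be gap-free and unambiguous for Ka/Ks", call. = FALSE)
  }
  aa_a <- translate_codon(codons_a, gc)
  aa_b <- translate_codon(codons_b, gc)
  nc <- length(codons_a)
  # drop a shared terminal stop; any other stop is an integrity error
  if (aa_a[nc] == "*" && aa_b[nc] == "*") {
    codons_a <- codons_a[-nc]; codons_b <- codons_b[-nc]
    aa_a <- aa_a[-nc]; aa_b <- aa_b[-nc]
    nc <- nc - 1L
  }
  if (any(aa_a == "*") || any(aa_b == "*")) {
    stop("internal stop codon in coding sequence", call. = FALSE)
  }
  if (nc == 0L) stop("no codons left to compare", call. = FALSE)
  syn_memo <- new.env(parent = emptyenv())
  syn1 <- function(cd) {
    v <- syn_memo[[cd]]
    if (is.null(v)) { v <- syn_sites_codon(cd, gc); syn_memo[[cd]] <- v }
    v
  }
  sa <- vapply(codons_a, syn1, numeric(1))
  sb <- vapply(codons_b, syn1, numeric(1))
  S <- sum((sa + sb) / 2)
  N <- 3 * nc - S
  dmat <- vapply(seq_len(nc), function(i) {
    codon_path_diffs(codons_a[i], codons_b[i], gc)
  }, numeric(2))
  Sd <- sum(dmat["sd", ])
  Nd <- sum(dmat["nd", ])
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ps = if (S > 0) Sd / S else 0, pn = if (N > 0) Nd / N else 0)
}

#' Classify selective pressure from Ka and Ks
#'
#' `ka/ks > 1` is positive selection, `= 1` neutral, `< 1` purifying;
#' `ka = 0` with `ks > 0` is reported as strong purifying selection, and
#' `ks = 0` leaves the ratio undefined.
#'
#' @param ka,ks Non-negative substitution rates.
#' @return One of `"positive"`, `"neutral"`, `"purifying"`,
#'   `"strong_purifying"`, `"undefined"`.
#' @export
classify_selection <- function(ka, ks) {
  if (is.na(ka) || is.na(ks) || ka < 0 || ks < 0) {
    stop("ka and ks must be non-negative", call. = FALSE)
  }
  if (ks == 0) return("undefined")
  if (ka == 0) return("strong_purifying")
  r <- ka / ks
  if (r > 1) "positive" else if (r == 1) "neutral" else "purifying"
}
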