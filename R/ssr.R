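## MISA-style perfect microsatellite scanning with named parameter presets,
## compound-SSR joining, and motif-class normalization.

SSR_PRESETS <- list(
  strict           = c(10L, 6L, 5L, 5L, 5L, 5L),
  melotto_modified = c(8L, 5L, 3L, 3L, 3L, 3L),
  relaxed          = c(10L, 5L, 4L, 3L, 2L, 2L)
)

#' SSR scanning preset
#'
#' Minimum repeat counts per unit size (1-6 bp). Three named presets are
#' bundled: `strict` (1/10, 2/6, 3/5, 4/5, 5/5, 6/5),
#' `melotto_modified` (1/8, 2/5, 3/3, 4/3, 5/3, 6/3) and
#' `relaxed` (1/10, 2/5, 3/4, 4/3, 5/2, 6/2).
#'
#' @param name Preset name, or ignored when `thresholds` is given.
#' @param thresholds Optional integer vector of six minimum repeat counts.
#' @return Object of class `ssr_preset`.
#' @export
ssr_preset <- function(name = c("strict", "melotto_modified", "relaxed"),
                       thresholds = NULL) {
  if (is.null(thresholds)) {
    name <- match.arg(name)
    thresholds <- SSR_PRESETS[[name]]
  } else {
    name <- if (is.character(name) && length(name) == 1L) name else "custom"
    stopifnot(length(thresholds) == 6L, all(thresholds >= 1L))
    thresholds <- as.integer(thresholds)
  }
  structure(list(name = name,
                 thresholds = stats::setNames(thresholds, 1:6)),
            class = "ssr_preset")
}

## is the motif primitive, i.e. not itself a repetition of a shorter unit?
is_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        motif == paste(rep(substr(motif, 1L, d), u / d), collapse = "")) {
      return(FALSE)
    }
  }
  TRUE
}

## canonical class of a motif: lexicographic minimum over all rotations of
## the motif and of its reverse complement; label "<canonical>/<revcomp>"
motif_class <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    rots <- function(x) {
      vapply(seq_len(u), function(i) {
        paste0(substr(x, i, u), substr(x, 1L, i - 1L))
      }, character(1))
    }
    can <- min(c(rots(m), rots(revcomp(m))))
    paste0(can, "/", revcomp(can))
  }, character(1), USE.NAMES = FALSE)
}

#' Scan a sequence for perfect microsatellites
#'
#' Finds maximal perfect tandem runs of 1-6 bp units meeting the preset's
#' minimum repeat count. A run is attributed to its smallest repeating unit
#' (a poly-AT stretch is one dinucleotide SSR, not a chain of mononucleotide
#' pairs), and when runs of different unit sizes overlap the smaller unit
#' takes precedence. Runs are trimmed to whole repeats. Coordinates are
#' 1-based inclusive.
#'
#' @param sequence Nucleotide string or [genome_record()].
#' @param preset An [ssr_preset()] (default `strict`).
#' @return data.frame with `motif`, `unit_size`, `repeats`, `start`, `end`,
#'   `size`, `ssr` (a `"(A)13"`-style label) and `class` (normalized motif
#'   class such as `"A/T"`), sorted by `start`.
#' @export
find_ssrs <- function(sequence, preset = ssr_preset("strict")) {
  s <- if (inherits(sequence, "genome_record")) sequence$sequence else
    toupper(sequence)
  stopifnot(inherits(preset, "ssr_preset"), nzchar(s))
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(sv)
  cand <- list()
  for (u in 1:6) {
    minrep <- preset$thresholds[[u]]
    if (n < u * minrep) next
    eq <- sv[(u + 1L):n] == sv[1:(n - u)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    for (i in w) {
      t0 <- starts[i]                 # run occupies bases t0 .. ends[i]+u
      total <- r$lengths[i] + u
      reps <- total %/% u
      if (reps < minrep) next
      motif <- substr(s, t0, t0 + u - 1L)
      if (grepl("[^ACGT]", motif) || !is_primitive(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        motif = motif, unit_size = u, repeats = reps,
        start = t0, end = t0 + reps * u - 1L
      )
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(motif = character(0), unit_size = integer(0),
                      repeats = integer(0), start = integer(0),
                      end = integer(0), size = integer(0),
                      ssr = character(0), class = character(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$unit_size, cand$start), , drop = FALSE]
  taken <- logical(n)
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
  res$size <- res$repeats * res$unit_size
  res$ssr <- sprintf("(%s)%d", res$motif, res$repeats)
  res$class <- motif_class(res$motif)
  rownames(res) <- NULL
  res
}

#' Join nearby SSRs into compound formations
#'
#' Consecutive SSRs separated by at most `max_gap` non-repetitive bases
#' share a compound id. Constituents keep their individual identity (counts
#' of SSRs found include each constituent); the compound span runs from the
#' first constituent's start to the last one's end.
#'
#' @param records data.frame from [find_ssrs()].
#' @param max_gap Maximum gap in bp between constituents (default 100).
#' @return `records` with a `compound_id` column (`NA` for simple SSRs);
#'   the summary of each compound is attached as attribute `"compounds"`
#'   (data.frame `compound_id`, `n`, `start`, `end`, `span`).
#' @export
join_compounds <- function(records, max_gap = 100L) {
  records <- records[order(records$start), , drop = FALSE]
  nr <- nrow(records)
  records$compound_id <- rep(NA_character_, nr)
  if (nr == 0L) {
    attr(records, "compounds") <- data.frame(
      compound_id = character(0), n = integer(0), start = integer(0),
      end = integer(0), span = integer(0))
    return(records)
  }
  gap_prev <- c(Inf, records$start[-1L] - records$end[-nr] - 1L)
  grp <- cumsum(gap_prev > max_gap)
  sizes <- table(grp)
  comp_groups <- names(sizes)[sizes > 1L]
  ids <- stats::setNames(paste0("C", seq_along(comp_groups)), comp_groups)
  records$compound_id <- unname(ids[as.character(grp)])
  comp <- do.call(rbind, lapply(comp_groups, function(g) {
    d <- records[grp == g, ]
    data.frame(compound_id = ids[[g]], n = nrow(d), start = min(d$start),
               end = max(d$end), span = max(d$end) - min(d$start) + 1L)
  }))
  if (is.null(comp)) {
    comp <- data.frame(compound_id = character(0), n = integer(0),
                       start = integer(0), end = integer(0),
                       span = integer(0))
  }
  attr(records, "compounds") <- comp
  rownames(records) <- NULL
  records
}

#' Tabulate SSRs by normalized motif class and unit size
#'
#' Motif normalization merges a motif, its rotations, and the reverse
#' complements thereof into one class (so A and T repeats both count as
#' `A/T`).
#'
#' @param records data.frame from [find_ssrs()].
#' @return List with `by_class` and `by_unit` count data.frames.
#' @export
classify_motifs <- function(records) {
  if (nrow(records) == 0L) {
    return(list(
      by_class = data.frame(class = character(0), n = integer(0)),
      by_unit = data.frame(unit_size = integer(0), n = integer(0))
    ))
  }
  bc <- as.data.frame(table(class = records$class),
                      responseName = "n", stringsAsFactors = FALSE)
  bu <- as.data.frame(table(unit_size = records$unit_size),
                      responseName = "n", stringsAsFactors = FALSE)
  bu$unit_size <- as.integer(bu$unit_size)
  list(by_class = bc[order(-bc$n), ], by_unit = bu)
}
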