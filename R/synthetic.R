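## Synthetic plastome-pair generator. Genome A is assembled as
## LSC + IRb + SSC + revcomp(IRb); genome B is derived from A by applying a
## SNP/indel specification exactly. Everything planted (genes, SNPs, indels,
## SSRs, partition coordinates, junction-gene offsets) is returned in a
## truth table so downstream modules can be validated against known answers.

#' Default SNP specification for the synthetic pair
#'
#' 24 coding point substitutions mirroring the class mix observed between
#' the two sugarcane ancestor plastomes: 12 transitions and 12
#' transversions, 6 synonymous and 18 nonsynonymous, spread over ten
#' single-copy genes with one ccsA-like gene carrying five.
#'
#' @return data.frame with `gene`, `codon_position`, `substitution_class`,
#'   `coding_effect`.
#' @export
default_snp_spec <- function() {
  spec <- rbind(
    # five synonymous transitions at codon position 3
    data.frame(gene = c("geneA01", "geneA02", "geneA04", "geneA05", "jsbG"),
               codon_position = 3L, substitution_class = "transition",
               coding_effect = "synonymous"),
    # seven nonsynonymous transitions
    data.frame(gene = c("geneA01", "geneA02", "geneA03", "geneA04",
                        "geneA06", "jlaG", "jlbG"),
               codon_position = c(1L, 2L, 1L, 1L, 2L, 1L, 2L),
               substitution_class = "transition",
               coding_effect = "nonsynonymous"),
    # one synonymous transversion at codon position 3
    data.frame(gene = "geneA05", codon_position = 3L,
               substitution_class = "transversion",
               coding_effect = "synonymous"),
    # eleven nonsynonymous transversions
    data.frame(gene = c("geneA03", "geneA03", "geneA03", "geneA03",
                        "geneA06", "jsaG", "jsbG", "geneA01", "geneA02",
                        "geneA04", "geneA05"),
               codon_position = c(1L, 2L, 3L, 1L, 1L, 3L, 1L, 3L, 1L,
                                  2L, 1L),
               substitution_class = "transversion",
               coding_effect = "nonsynonymous")
  )
  spec
}

#' Default indel specification
#'
#' Three small intergenic indels: two insertions present only in genome B
#' and one deletion from genome B, in the LSC and SSC.
#'
#' @return data.frame with `region`, `type`, `length`.
#' @export
default_indel_spec <- function() {
  data.frame(region = c("lsc", "lsc", "ssc"),
             type = c("insertion_b", "deletion_b", "insertion_b"),
             length = c(6L, 10L, 8L))
}

#' Default SSR specification
#'
#' Intergenic plantings exercising the scanner: a (A)13 and a (G)10
#' mononucleotide run, a (T)10 + 8 bp + (T)10 compound formation (28 bp
#' span), an (AT)6 dinucleotide and an (AAG)5 trinucleotide.
#'
#' @return data.frame with `motif`, `repeats`, `region`, `compound_group`,
#'   `gap_before` (bp of non-repetitive gap separating a compound member
#'   from the previous one).
#' @export
default_ssr_spec <- function() {
  data.frame(
    motif = c("A", "T", "T", "AT", "G", "AAG"),
    repeats = c(13L, 10L, 10L, 6L, 10L, 5L),
    region = c("lsc", "lsc", "lsc", "lsc", "lsc", "ssc"),
    compound_group = c(NA, 1L, 1L, NA, NA, NA),
    gap_before = c(NA, NA, 8L, NA, NA, NA)
  )
}

#' Default junction-gene placement
#'
#' One boundary gene per junction mirroring the published offsets: a 58 bp
#' contraction at JLB (rpl22-like), a gene spanning JSB with 29 bp expanded
#' into the IRb (ndhF-like), a 153 bp contraction at JSA (rps15-like) and a
#' 90 bp contraction at JLA (psbA-like).
#'
#' @return data.frame with `junction`, `gene`, `region`, `gap`,
#'   `span_into`.
#' @export
default_junction_spec <- function() {
  data.frame(
    junction = c("JLB", "JSB", "JSA", "JLA"),
    gene = c("jlbG", "jsbG", "jsaG", "jlaG"),
    region = c("lsc", "ssc", "ssc", "lsc"),
    gap = c(58L, 0L, 153L, 90L),
    span_into = c(0L, 29L, 0L, 0L)
  )
}

#' Synthetic plastome-pair configuration
#'
#' The desk-scale default is a 14 kb quadripartite genome (LSC 8400, IR
#' 2100 each, SSC 1400) carrying 12 genes and the default SNP/indel/SSR/
#' junction specifications; `scale = "full"` gives a 140 kb layout with the
#' same structure. Identical configuration and seed produce byte-identical
#' output.
#'
#' @param total_length Total genome length in bp.
#' @param region_lengths Named numeric vector `(lsc, irb, ssc)`; the
#'   implied IRa has IRb's length and the four must sum to `total_length`.
#' @param n_genes Number of distinct genes (>= 6): four junction genes, one
#'   IR-duplicated gene, the rest regular LSC genes (of which the last is
#'   flagged trans-spliced).
#' @param snp_spec,indel_spec,ssr_spec,junction_gene_spec Specification
#'   data.frames; see the `default_*_spec()` helpers.
#' @param seed Integer seed.
#' @param scale `"desk"` or `"full"`; presets `total_length` and
#'   `region_lengths` when those are missing.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(total_length = NULL, region_lengths = NULL,
                             n_genes = 12L,
                             snp_spec = default_snp_spec(),
                             indel_spec = default_indel_spec(),
                             ssr_spec = default_ssr_spec(),
                             junction_gene_spec = default_junction_spec(),
                             seed = 42L, scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (is.null(total_length)) {
    total_length <- if (scale == "desk") 14000L else 140000L
  }
  if (is.null(region_lengths)) {
    region_lengths <- if (scale == "desk") {
      c(lsc = 8400L, irb = 2100L, ssc = 1400L)
    } else {
      c(lsc = 84000L, irb = 21000L, ssc = 14000L)
    }
  }
  region_lengths <- stats::setNames(as.integer(region_lengths),
                                    c("lsc", "irb", "ssc"))
  if (sum(region_lengths) + region_lengths["irb"] != total_length) {
    stop("region lengths + implied IRa must sum to total_length",
         call. = FALSE)
  }
  if (n_genes < 6L) stop("n_genes must be at least 6", call. = FALSE)
  structure(
    list(total_length = as.integer(total_length),
         region_lengths = region_lengths, n_genes = as.integer(n_genes),
         snp_spec = snp_spec, indel_spec = indel_spec, ssr_spec = ssr_spec,
         junction_gene_spec = junction_gene_spec, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random CDS of n_codons codons: ATG start, no internal stop, stop at end
rand_cds <- function(n_codons, gc = codon_table()) {
  nonstop <- names(gc)[gc != "*"]
  body <- sample(nonstop, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

#' Plant perfect microsatellites into a sequence
#'
#' Overwrites the sequence with the requested tandem runs at the given
#' starts and breaks the periodic continuation at each flank, so a scanner
#' recovers exactly the planted coordinates. Overlapping plant locations
#' (including their 1 bp flanks) are a specification error.
#'
#' @param sequence Nucleotide string.
#' @param ssr_spec data.frame with `motif`, `repeats`, `start`.
#' @return List with `sequence` and `planted` (data.frame `motif`,
#'   `repeats`, `start`, `end`).
#' @export
plant_ssrs <- function(sequence, ssr_spec) {
  stopifnot(all(c("motif", "repeats", "start") %in% names(ssr_spec)))
  sv <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(sv)
  spec <- ssr_spec[order(ssr_spec$start), , drop = FALSE]
  spec$end <- spec$start + nchar(spec$motif) * spec$repeats - 1L
  if (any(spec$end > n) || any(spec$start < 2L)) {
    stop("SSR plant location outside the sequence interior", call. = FALSE)
  }
  if (nrow(spec) > 1L &&
      any(spec$start[-1L] <= spec$end[-nrow(spec)] + 1L)) {
    bad <- which(spec$start[-1L] <= spec$end[-nrow(spec)] + 1L)[1L]
    stop("overlapping SSR plant locations: rows ", bad, " and ", bad + 1L,
         call. = FALSE)
  }
  for (i in seq_len(nrow(spec))) {
    u <- nchar(spec$motif[i])
    run <- strsplit(strrep(spec$motif[i], spec$repeats[i]), "")[[1]]
    sv[spec$start[i]:spec$end[i]] <- run
    # break periodic continuation at both flanks
    first <- substr(spec$motif[i], 1L, 1L)
    last <- substr(spec$motif[i], u, u)
    if (sv[spec$start[i] - 1L] == last) {
      sv[spec$start[i] - 1L] <- setdiff(c("A", "C", "G", "T"), last)[1L]
    }
    if (spec$end[i] < n && sv[spec$end[i] + 1L] == first) {
      sv[spec$end[i] + 1L] <- setdiff(c("A", "C", "G", "T"), first)[1L]
    }
  }
  list(sequence = paste(sv, collapse = ""),
       planted = spec[, c("motif", "repeats", "start", "end")])
}

## map a position in a spliced plus-direction CDS to genome coordinates
cds_pos_to_genome <- function(feature, cds_pos) {
  exlens <- feature$exons[, "end"] - feature$exons[, "start"] + 1L
  if (feature$strand == "+") {
    off <- cds_pos
    for (e in seq_len(nrow(feature$exons))) {
      if (off <= exlens[e]) return(feature$exons[e, "start"] + off - 1L)
      off <- off - exlens[e]
    }
  } else {
    off <- cds_pos
    for (e in rev(seq_len(nrow(feature$exons)))) {
      if (off <= exlens[e]) return(feature$exons[e, "end"] - off + 1L)
      off <- off - exlens[e]
    }
  }
  stop("cds position beyond feature length", call. = FALSE)
}

## pick a codon site satisfying (codon_position, class, effect) in cds;
## codons in `used` (and the first/last codon) are excluded
pick_snp_site <- function(cds, codon_position, substitution_class,
                          coding_effect, used, gc = codon_table()) {
  ncod <- nchar(cds) %/% 3L
  comp_ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv_alts <- list(A = c("C", "T"), G = c("C", "T"),
                  C = c("A", "G"), T = c("A", "G"))
  for (ci in sample(2:(ncod - 1L))) {
    if (ci %in% used) next
    codon <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
    ref <- substr(codon, codon_position, codon_position)
    alts <- if (substitution_class == "transition") {
      comp_ts[[ref]]
    } else {
      sample(tv_alts[[ref]])
    }
    for (alt in alts) {
      altc <- codon
      substr(altc, codon_position, codon_position) <- alt
      if (gc[[altc]] == "*") next
      eff <- if (gc[[codon]] == gc[[altc]]) "synonymous" else "nonsynonymous"
      if (eff == coding_effect) {
        return(list(codon_index = ci, ref_codon = codon, alt_codon = altc,
                    ref_base = ref, alt_base = alt))
      }
    }
  }
  NULL
}

#' Generate a synthetic plastome pair with ground truth
#'
#' Assembles genome A as LSC + IRb + SSC + revcomp(IRb) with planted genes,
#' junction genes, an IR-duplicated gene and SSRs; derives genome B by
#' applying the SNP and indel specifications exactly; and returns both
#' genomes, both annotation sets and a truth table. The same configuration
#' and seed reproduce byte-identical output.
#'
#' @param config A [synthetic_config()].
#' @return List with `genome_a`, `genome_b` ([genome_record()]s),
#'   `annot_a`, `annot_b` ([annotation_set()]s) and `truth`, a list with
#'   `snps`, `indels`, `ssrs`, `partition_a`, `partition_b`,
#'   `junction_genes` and `cds_a` (the planted coding strings).
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  L <- config$region_lengths[["lsc"]]
  I <- config$region_lengths[["irb"]]
  S <- config$region_lengths[["ssc"]]
  n <- config$total_length
  jlb <- L + 1L; jsb <- L + I + 1L; jsa <- L + I + S + 1L  # junction coords
  gc <- codon_table()

  ## ---- gene layout -------------------------------------------------
  jspec <- config$junction_gene_spec
  genes <- list()
  add_gene <- function(name, strand, exons, trans_spliced = FALSE,
                       copy_index = 1L, cds = NULL) {
    genes[[length(genes) + 1L]] <<- list(
      name = name, strand = strand, exons = exons,
      trans_spliced = trans_spliced, copy_index = copy_index, cds = cds)
  }
  glen <- function(n_codons) 3L * n_codons
  # junction genes (placed relative to their junction)
  for (r in seq_len(nrow(jspec))) {
    len <- glen(sample(80:110, 1L))
    jn <- jspec$junction[r]
    gap <- jspec$gap[r]; span <- jspec$span_into[r]
    iv <- switch(jn,
      JLB = if (span > 0L) c(jlb - len + span, jlb + span - 1L) else
        c(jlb - gap - len, jlb - gap - 1L),
      JSB = if (span > 0L) c(jsb - span, jsb - span + len - 1L) else
        c(jsb + gap, jsb + gap + len - 1L),
      JSA = if (span > 0L) c(jsa - len + span, jsa + span - 1L) else
        c(jsa - gap - len, jsa - gap - 1L),
      JLA = c(1L + gap, gap + len)
    )
    add_gene(jspec$gene[r], "+", cbind(start = iv[1], end = iv[2]))
  }
  # regular LSC genes between the JLA gene and half the LSC
  n_regular <- config$n_genes - nrow(jspec) - 1L
  jla_row <- which(jspec$junction == "JLA")
  cursor <- if (length(jla_row)) {
    jspec$gap[jla_row] + glen(110L) + 150L
  } else 200L
  limit <- floor(0.58 * L)   # genes stay clear of the SSR zone at 0.60*L
  for (g in seq_len(n_regular)) {
    ncod <- sample(80:130, 1L)
    len <- glen(ncod)
    strand <- if (g %% 2L == 0L) "-" else "+"
    trans_spliced <- g == n_regular       # last regular gene exercises rps12 handling
    two_exon <- g == 1L || trans_spliced
    intron <- if (two_exon) sample(60:120, 1L) else 0L
    if (cursor + len + intron > limit) {
      stop("gene layout overflow: LSC too small for n_genes", call. = FALSE)
    }
    nm <- sprintf("geneA%02d", g)
    if (two_exon) {
      e1 <- 3L * sample(20:40, 1L)
      exons <- cbind(start = c(cursor, cursor + e1 + intron),
                     end = c(cursor + e1 - 1L, cursor + len + intron - 1L))
    } else {
      exons <- cbind(start = cursor, end = cursor + len - 1L)
    }
    add_gene(nm, strand, exons, trans_spliced = trans_spliced)
    cursor <- cursor + len + intron + sample(120:200, 1L)
  }
  # IR-duplicated gene inside the IRb
  dup_len <- glen(sample(70:90, 1L))
  dup_start <- jlb + 200L
  add_gene("irdG", "+", cbind(start = dup_start,
                              end = dup_start + dup_len - 1L))

  ## ---- assemble genome A prefix (LSC + IRb + SSC) ------------------
  prefix_len <- L + I + S
  sv <- strsplit(rand_bases(prefix_len), "", fixed = TRUE)[[1]]
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    cds_len <- sum(g$exons[, "end"] - g$exons[, "start"] + 1L)
    cds <- rand_cds(cds_len %/% 3L, gc)
    genes[[gi]]$cds <- cds
    oriented <- if (g$strand == "+") cds else revcomp(cds)
    off <- 0L
    for (e in seq_len(nrow(g$exons))) {
      w <- g$exons[e, "end"] - g$exons[e, "start"] + 1L
      sv[g$exons[e, "start"]:g$exons[e, "end"]] <-
        strsplit(substr(oriented, off + 1L, off + w), "")[[1]]
      off <- off + w
    }
  }

  ## ---- plant SSRs ---------------------------------------------------
  sspec <- config$ssr_spec
  zone_start <- c(lsc = floor(0.60 * L), ssc = L + I + floor(0.30 * S))
  zone_cursor <- zone_start
  abs_spec <- NULL
  for (r in seq_len(nrow(sspec))) {
    reg <- sspec$region[r]
    width <- nchar(sspec$motif[r]) * sspec$repeats[r]
    if (!is.na(sspec$compound_group[r]) && !is.na(sspec$gap_before[r])) {
      start <- zone_cursor[reg] + sspec$gap_before[r]  # continue compound
    } else {
      start <- zone_cursor[reg] + 150L  # well beyond the compound max_gap
    }
    abs_spec <- rbind(abs_spec, data.frame(
      motif = sspec$motif[r], repeats = sspec$repeats[r], start = start,
      compound_group = sspec$compound_group[r]))
    zone_cursor[reg] <- start + width
  }
  if (!is.null(abs_spec)) {
    planted <- plant_ssrs(paste(sv, collapse = ""),
                          abs_spec[, c("motif", "repeats", "start")])
    sv <- strsplit(planted$sequence, "", fixed = TRUE)[[1]]
    ssr_truth <- planted$planted
    ssr_truth$compound_group <-
      abs_spec$compound_group[order(abs_spec$start)]
  } else {
    ssr_truth <- data.frame(motif = character(0), repeats = integer(0),
                            start = integer(0), end = integer(0),
                            compound_group = integer(0))
  }

  ## ---- close the quadripartite structure ---------------------------
  # break chance complementarity at the IR boundaries so maximal exact
  # extension recovers exactly the planted partition
  comp0 <- c(A = "T", C = "G", G = "C", T = "A")
  # JLA side: the last LSC base would pair, across the circular origin,
  # with the complement of base 1 and extend the IR
  if (sv[L] == comp0[[sv[1L]]]) {
    sv[L] <- setdiff(c("A", "C", "G", "T"),
                     c(comp0[[sv[1L]]], sv[L - 1L]))[1L]
  }
  if (sv[L + I + S] == comp0[[sv[L + I + 1L]]]) {
    sv[L + I + S] <- setdiff(c("A", "C", "G", "T"),
                             comp0[[sv[L + I + 1L]]])[1L]
  }
  irb_seq <- paste(sv[jlb:(jsb - 1L)], collapse = "")
  seq_a <- paste0(paste(sv, collapse = ""), revcomp(irb_seq))
  genome_a <- genome_record("synthA", seq_a)

  # annotation set A (IR-duplicated gene gets a mirrored second copy)
  feats_a <- list()
  for (g in genes) {
    feats_a[[length(feats_a) + 1L]] <- gene_feature(
      g$name, "CDS", g$strand, g$exons, trans_spliced = g$trans_spliced)
  }
  irb_end <- jsb - 1L; ira_start <- jsa
  mirror <- function(p) ira_start + (irb_end - p)
  dup <- genes[[length(genes)]]
  feats_a[[length(feats_a) + 1L]] <- gene_feature(
    dup$name, "CDS", "-",
    cbind(start = mirror(dup$exons[1, "end"]),
          end = mirror(dup$exons[1, "start"])),
    copy_index = 2L)
  annot_a <- annotation_set("synthA", feats_a)

  ## ---- plan SNPs ----------------------------------------------------
  snp_spec <- config$snp_spec
  used <- list()
  snp_rows <- list()
  subs <- NULL   # genomic substitutions to apply to B
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in seq_len(nrow(snp_spec))) {
    gname <- snp_spec$gene[r]
    gi <- which(vapply(genes, function(g) g$name, character(1)) == gname)
    if (length(gi) != 1L) {
      stop("snp_spec names unknown gene '", gname, "'", call. = FALSE)
    }
    g <- genes[[gi]]
    site <- pick_snp_site(g$cds, snp_spec$codon_position[r],
                          snp_spec$substitution_class[r],
                          snp_spec$coding_effect[r],
                          used[[gname]] %||% integer(0), gc)
    if (is.null(site)) {
      stop("infeasible snp_spec row ", r, ": no ",
           snp_spec$coding_effect[r], " ", snp_spec$substitution_class[r],
           " available at codon position ", snp_spec$codon_position[r],
           " in gene ", gname, call. = FALSE)
    }
    used[[gname]] <- c(used[[gname]] %||% integer(0), site$codon_index)
    cds_pos <- (site$codon_index - 1L) * 3L + snp_spec$codon_position[r]
    feat <- gene_feature(g$name, "CDS", g$strand, g$exons)
    gpos <- cds_pos_to_genome(feat, cds_pos)
    base_b <- if (g$strand == "+") site$alt_base else comp[[site$alt_base]]
    subs <- rbind(subs, data.frame(pos = gpos, base = base_b))
    cls <- classify_substitution(site$ref_base, site$alt_base)
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      gene_name = gname, copy_index = 1L, gene_position = cds_pos,
      codon_index = site$codon_index,
      codon_position = snp_spec$codon_position[r],
      ref_base = site$ref_base, alt_base = site$alt_base,
      ref_codon = site$ref_codon, alt_codon = site$alt_codon,
      ref_aa = gc[[site$ref_codon]], alt_aa = gc[[site$alt_codon]],
      substitution_class = cls$substitution_class,
      ts_subtype = cls$ts_subtype,
      coding_effect = snp_spec$coding_effect[r],
      genome_pos_a = gpos
    )
  }
  snp_truth <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(gene_name = character(0), copy_index = integer(0),
               gene_position = integer(0), codon_index = integer(0),
               codon_position = integer(0), ref_base = character(0),
               alt_base = character(0), ref_codon = character(0),
               alt_codon = character(0), ref_aa = character(0),
               alt_aa = character(0), substitution_class = character(0),
               ts_subtype = character(0), coding_effect = character(0),
               genome_pos_a = integer(0))
  snp_truth <- snp_truth[order(snp_truth$gene_name,
                               snp_truth$gene_position), , drop = FALSE]
  rownames(snp_truth) <- NULL

  ## ---- plan indels --------------------------------------------------
  ispec <- config$indel_spec
  indel_zone <- c(lsc = floor(0.84 * L), ssc = L + I + floor(0.63 * S))
  izone_cursor <- indel_zone
  indels <- NULL
  for (r in seq_len(nrow(ispec))) {
    reg <- ispec$region[r]
    pos <- izone_cursor[reg] + 30L      # indel sits after this A position
    izone_cursor[reg] <- pos + ispec$length[r] + 30L
    indels <- rbind(indels, data.frame(
      region = reg, type = ispec$type[r], pos_a = pos,
      length = ispec$length[r]))
  }

  ## ---- build genome B ----------------------------------------------
  bv <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  if (!is.null(subs)) bv[subs$pos] <- subs$base
  if (!is.null(indels)) {
    for (r in order(-indels$pos_a)) {
      p <- indels$pos_a[r]; l <- indels$length[r]
      if (indels$type[r] == "insertion_b") {
        ins <- strsplit(rand_bases(l), "", fixed = TRUE)[[1]]
        bv <- append(bv, ins, after = p)
      } else {
        bv <- bv[-((p + 1L):(p + l))]
      }
    }
  }
  genome_b <- genome_record("synthB", paste(bv, collapse = ""))

  # coordinate shift A -> B implied by the indels
  shift_b <- function(p) {
    s <- p
    if (!is.null(indels)) {
      for (r in seq_len(nrow(indels))) {
        if (indels$pos_a[r] < p) {
          s <- s + if (indels$type[r] == "insertion_b") {
            indels$length[r]
          } else {
            -indels$length[r]
          }
        }
      }
    }
    s
  }
  feats_b <- lapply(feats_a, function(f) {
    ex <- f$exons
    ex[, "start"] <- vapply(ex[, "start"], shift_b, numeric(1))
    ex[, "end"] <- vapply(ex[, "end"], shift_b, numeric(1))
    gene_feature(f$gene_name, f$feature_type, f$strand, ex,
                 trans_spliced = f$trans_spliced, copy_index = f$copy_index)
  })
  annot_b <- annotation_set("synthB", feats_b)
  snp_truth$genome_pos_b <- vapply(snp_truth$genome_pos_a, shift_b,
                                   numeric(1))
  ssr_truth$start_b <- vapply(ssr_truth$start, shift_b, numeric(1))
  ssr_truth$end_b <- vapply(ssr_truth$end, shift_b, numeric(1))

  ## ---- truth: partitions and junction offsets ----------------------
  part_a <- quadripartite_partition(
    lsc = c(1L, L), irb = c(jlb, jsb - 1L), ssc = c(jsb, jsa - 1L),
    ira = c(jsa, n), genome_length = n)
  dL <- if (is.null(indels)) 0L else {
    sum(ifelse(indels$region == "lsc",
               ifelse(indels$type == "insertion_b", indels$length,
                      -indels$length), 0L))
  }
  dS <- if (is.null(indels)) 0L else {
    sum(ifelse(indels$region == "ssc",
               ifelse(indels$type == "insertion_b", indels$length,
                      -indels$length), 0L))
  }
  Lb <- L + dL; Sb <- S + dS; nb <- n + dL + dS
  part_b <- quadripartite_partition(
    lsc = c(1L, Lb), irb = c(Lb + 1L, Lb + I),
    ssc = c(Lb + I + 1L, Lb + I + Sb), ira = c(Lb + I + Sb + 1L, nb),
    genome_length = nb)

  list(
    genome_a = genome_a, genome_b = genome_b,
    annot_a = annot_a, annot_b = annot_b,
    truth = list(
      snps = snp_truth,
      indels = if (is.null(indels)) {
        data.frame(region = character(0), type = character(0),
                   pos_a = integer(0), length = integer(0))
      } else indels,
      ssrs = ssr_truth,
      partition_a = part_a, partition_b = part_b,
      junction_genes = jspec,
      cds_a = stats::setNames(
        vapply(genes, function(g) g$cds, character(1)),
        vapply(genes, function(g) g$name, character(1)))
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
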