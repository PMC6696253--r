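## Full two-genome comparison: orchestrates structure detection, alignment,
## divergence statistics, SNP calling, codon usage, junction analysis and
## SSR scanning into one reproducible report bundle.

#' Compare the partitions of two genomes
#'
#' Signed per-region length differences (genome A minus genome B) plus a
#' total row. The IRs are listed separately, so the total delta equals the
#' genome length difference.
#'
#' @param partition_a,partition_b [quadripartite_partition()]s.
#' @return data.frame with `region`, `length_a`, `length_b`, `delta`.
#' @export
validate_structure <- function(partition_a, partition_b) {
  regions <- c("lsc", "irb", "ssc", "ira")
  la <- partition_a$region_lengths[regions]
  lb <- partition_b$region_lengths[regions]
  out <- data.frame(
    region = c(toupper(regions), "total"),
    length_a = as.integer(c(la, partition_a$genome_length)),
    length_b = as.integer(c(lb, partition_b$genome_length)),
    delta = as.integer(c(la - lb,
                         partition_a$genome_length -
                           partition_b$genome_length))
  )
  rownames(out) <- NULL
  out
}

write_report_tsv <- function(df, path, title, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", title),
               "# coordinates: 1-based inclusive",
               paste0("# ", extra)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full two-genome comparison
#'
#' Executes every stage of the comparative analysis in order -- structure
#' detection and validation, whole-genome anchor alignment, sliding-window
#' Pi with hotspot calling, per-gene K2P and Ka/Ks with selection
#' classification, coding SNP calling and summary, codon usage and RSCU,
#' IR junction reports, and SSR scans under one or more presets -- and
#' returns the tables as a list. When `out_dir` is given the tables are
#' also written as commented TSVs together with a JSON manifest recording
#' every parameter, so a run can be reproduced exactly.
#'
#' @param genome_a,genome_b [genome_record()]s.
#' @param annot_a,annot_b [annotation_set()]s.
#' @param out_dir Optional output directory (created if needed).
#' @param window,step Sliding-window parameters in bp.
#' @param hotspot_threshold Strict Pi threshold for hotspot calling.
#' @param ssr_presets Character vector of preset names.
#' @param flank Junction reporting distance in bp.
#' @param k,band Anchor alignment parameters.
#' @param min_ir_len Minimum inverted-repeat length in bp.
#' @param skip_trans_spliced Exclude trans-spliced genes from CDS-level
#'   stages.
#' @return List with `structure`, `partition_a`, `partition_b`,
#'   `alignment`, `pi_track`, `hotspots`, `gene_divergence`, `snps`,
#'   `snp_summary`, `codon_usage_a`, `codon_usage_b`, `aa_freq_a`,
#'   `aa_freq_b`, `junctions_a`, `junctions_b`, `ssr` (per preset, per
#'   genome) and `manifest`.
#' @export
run_compare <- function(genome_a, genome_b, annot_a, annot_b,
                        out_dir = NULL, window = 600L, step = 200L,
                        hotspot_threshold = 0.006,
                        ssr_presets = c("strict", "melotto_modified",
                                        "relaxed"),
                        flank = 1000L, k = 21L, band = 64L,
                        min_ir_len = 1000L, skip_trans_spliced = TRUE) {
  stopifnot(window > 0, step > 0, hotspot_threshold > 0, flank > 0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  part_a <- stage("structure", find_inverted_repeats(genome_a, min_ir_len))
  part_b <- stage("structure", find_inverted_repeats(genome_b, min_ir_len))
  structure_tab <- validate_structure(part_a, part_b)

  aln <- stage("alignment", anchor_align(genome_a, genome_b, k = k,
                                         band = band))
  pi_track <- stage("diversity", sliding_pi(aln, window, step))
  hotspots <- stage("diversity", detect_hotspots(pi_track,
                                                 hotspot_threshold))

  cds_a <- stage("cds", extract_cds(genome_a, annot_a, skip_trans_spliced))
  cds_b <- stage("cds", extract_cds(genome_b, annot_b, skip_trans_spliced))
  shared <- intersect(names(cds_a), names(cds_b))
  gene_div <- stage("divergence", {
    rows <- lapply(shared, function(nm) {
      cols <- align_gene_pair(cds_a[[nm]], cds_b[[nm]])
      kp <- k2p_distance(cols)
      kk <- ng86_kaks(cds_a[[nm]], cds_b[[nm]])
      data.frame(gene = nm, k2p = kp$d, P = kp$P, Q = kp$Q,
                 ka = kk$ka, ks = kk$ks, ka_ks = kk$ka_ks,
                 selection = classify_selection(kk$ka, kk$ks))
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })

  snps <- stage("snps", call_snps(genome_a, genome_b, annot_a, annot_b,
                                  skip_trans_spliced))
  snp_summary <- summarize_snps(snps)

  usage_a <- stage("codons", count_codons(cds_a))
  usage_b <- stage("codons", count_codons(cds_b))
  rscu_a <- rscu(usage_a); rscu_b <- rscu(usage_b)
  aa_a <- aa_frequencies(usage_a); aa_b <- aa_frequencies(usage_b)

  junc_a <- stage("junctions", junction_offsets(part_a, annot_a, flank))
  junc_b <- stage("junctions", junction_offsets(part_b, annot_b, flank))

  ssr <- stage("ssr", {
    out <- list()
    for (p in ssr_presets) {
      preset <- ssr_preset(p)
      out[[p]] <- list(
        a = join_compounds(find_ssrs(genome_a, preset)),
        b = join_compounds(find_ssrs(genome_b, preset))
      )
    }
    out
  })

  manifest <- list(
    package = "plastcompare",
    version = as.character(utils::packageVersion("plastcompare")),
    genome_a = list(id = genome_a$id, length = genome_a$length),
    genome_b = list(id = genome_b$id, length = genome_b$length),
    parameters = list(window = window, step = step,
                      hotspot_threshold = hotspot_threshold,
                      ssr_presets = ssr_presets, flank = flank, k = k,
                      band = band, min_ir_len = min_ir_len,
                      skip_trans_spliced = skip_trans_spliced)
  )

  bundle <- list(
    structure = structure_tab, partition_a = part_a, partition_b = part_b,
    alignment = aln, pi_track = pi_track, hotspots = hotspots,
    gene_divergence = gene_div, snps = snps, snp_summary = snp_summary,
    codon_usage_a = rscu_a, codon_usage_b = rscu_b,
    aa_freq_a = aa_a, aa_freq_b = aa_b,
    junctions_a = junc_a, junctions_b = junc_b,
    ssr = ssr, manifest = manifest
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- paste(bundle$manifest$genome_a$id, "vs",
               bundle$manifest$genome_b$id)
  w <- function(df, file, title) {
    write_report_tsv(df, file.path(out_dir, file), paste(title, "--", ids))
  }
  w(bundle$structure, "structure.tsv", "quadripartite structure summary")
  w(bundle$pi_track, "pi_track.tsv", "sliding-window nucleotide diversity")
  w(bundle$hotspots, "hotspots.tsv", "divergence hotspots")
  w(bundle$gene_divergence, "gene_divergence.tsv",
    "per-gene K2P / Ka / Ks")
  w(bundle$snps, "snps.tsv", "coding SNP records")
  w(bundle$codon_usage_a, "codon_usage_a.tsv", "codon usage / RSCU (A)")
  w(bundle$codon_usage_b, "codon_usage_b.tsv", "codon usage / RSCU (B)")
  w(bundle$aa_freq_a, "aa_frequencies_a.tsv", "amino-acid frequencies (A)")
  w(bundle$aa_freq_b, "aa_frequencies_b.tsv", "amino-acid frequencies (B)")
  w(bundle$junctions_a, "junctions_a.tsv", "IR junction report (A)")
  w(bundle$junctions_b, "junctions_b.tsv", "IR junction report (B)")
  for (p in names(bundle$ssr)) {
    w(bundle$ssr[[p]]$a, sprintf("ssr_%s_a.tsv", p),
      sprintf("SSRs, preset %s (A)", p))
    w(bundle$ssr[[p]]$b, sprintf("ssr_%s_b.tsv", p),
      sprintf("SSRs, preset %s (B)", p))
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
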