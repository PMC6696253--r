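# synthetic plastome-pair generator: determinism, construction invariants,
# specification handling

test_that("identical config and seed give byte-identical output", {
  a <- generate_pair(synthetic_config(seed = 701))
  b <- generate_pair(synthetic_config(seed = 701))
  expect_identical(a$genome_a$sequence, b$genome_a$sequence)
  expect_identical(a$genome_b$sequence, b$genome_b$sequence)
  expect_identical(a$truth$snps, b$truth$snps)
  expect_identical(a$truth$ssrs, b$truth$ssrs)
  c_ <- generate_pair(synthetic_config(seed = 702))
  expect_false(identical(a$genome_a$sequence, c_$genome_a$sequence))
})

test_that("IRa equals the reverse complement of IRb by construction", {
  cfg <- synthetic_config(total_length = 13200L,
                          region_lengths = c(lsc = 8000L, irb = 2000L,
                                             ssc = 1200L),
                          seed = 703)
  pair <- generate_pair(cfg)
  p <- pair$truth$partition_a
  s <- pair$genome_a$sequence
  irb <- substr(s, p$irb[1], p$irb[2])
  ira <- substr(s, p$ira[1], p$ira[2])
  expect_equal(ira, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(irb))))
  expect_equal(pair$genome_a$length, 13200L)
})

test_that("empty mutation specs give identical genomes", {
  cfg <- synthetic_config(
    snp_spec = default_snp_spec()[0, ],
    indel_spec = default_indel_spec()[0, ],
    seed = 704)
  pair <- generate_pair(cfg)
  expect_identical(pair$genome_a$sequence, pair$genome_b$sequence)
  expect_equal(nrow(pair$truth$snps), 0L)
  expect_equal(nrow(pair$truth$indels), 0L)
})

test_that("a single planted synonymous transition round-trips the pipeline", {
  cfg <- synthetic_config(
    snp_spec = data.frame(gene = "geneA01", codon_position = 3L,
                          substitution_class = "transition",
                          coding_effect = "synonymous"),
    indel_spec = default_indel_spec()[0, ],
    seed = 705)
  pair <- generate_pair(cfg)
  expect_equal(nrow(pair$truth$snps), 1L)
  rec <- call_snps(pair$genome_a, pair$genome_b, pair$annot_a,
                   pair$annot_b)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$coding_effect, "synonymous")
  expect_equal(rec$substitution_class, "transition")
  expect_equal(rec$codon_position, 3L)
})

test_that("infeasible SNP requests raise a spec error naming the entry", {
  # a transversion at codon position 3 of a Met codon can be synonymous
  # nowhere if the gene lacks suitable codons; force infeasibility with a
  # contradictory request: synonymous change in a gene made of ATG codons
  # is impossible at codon positions 1 and 2
  cfg <- synthetic_config(
    snp_spec = data.frame(gene = "no_such_gene", codon_position = 1L,
                          substitution_class = "transition",
                          coding_effect = "synonymous"),
    seed = 706)
  expect_error(generate_pair(cfg), "unknown gene")
})

test_that("planted SSRs appear verbatim at recorded coordinates", {
  pair <- generate_pair(synthetic_config(seed = 707))
  s <- pair$genome_a$sequence
  for (r in seq_len(nrow(pair$truth$ssrs))) {
    t <- pair$truth$ssrs[r, ]
    expect_equal(substr(s, t$start, t$end),
                 strrep(t$motif, t$repeats), info = t$motif)
  }
  # and in genome B at the shifted coordinates
  sb <- pair$genome_b$sequence
  for (r in seq_len(nrow(pair$truth$ssrs))) {
    t <- pair$truth$ssrs[r, ]
    expect_equal(substr(sb, t$start_b, t$end_b),
                 strrep(t$motif, t$repeats))
  }
})

test_that("plant_ssrs rejects overlapping locations and validates bounds", {
  s <- strrep("CGCGT", 40)
  expect_error(plant_ssrs(s, data.frame(motif = c("A", "T"),
                                        repeats = c(10L, 10L),
                                        start = c(20L, 25L))),
               "overlapping")
  expect_error(plant_ssrs(s, data.frame(motif = "A", repeats = 50L,
                                        start = 190L)), "outside")
  got <- plant_ssrs(s, data.frame(motif = "AT", repeats = 6L, start = 50L))
  expect_equal(substr(got$sequence, 50, 61), strrep("AT", 6))
  expect_equal(got$planted$end, 61L)
})

test_that("region lengths must be consistent with the total", {
  expect_error(synthetic_config(total_length = 10000L,
                                region_lengths = c(lsc = 8000L,
                                                   irb = 2000L,
                                                   ssc = 1200L)),
               "sum")
})

test_that("the full-scale configuration also assembles and validates", {
  cfg <- synthetic_config(scale = "full", seed = 708)
  pair <- generate_pair(cfg)
  expect_equal(pair$genome_a$length, 140000L)
  p <- find_inverted_repeats(pair$genome_a, min_len = 1000)
  expect_equal(p$irb, pair$truth$partition_a$irb)
  expect_equal(p$ssc, pair$truth$partition_a$ssc)
})
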