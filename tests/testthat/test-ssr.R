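# MISA-style SSR scanning, presets, compound joining, motif classes

test_that("forced worked examples under the strict preset", {
  strict <- ssr_preset("strict")
  got <- find_ssrs(paste0("CC", strrep("A", 13), "GG"), strict)
  expect_equal(nrow(got), 1L)
  expect_equal(got$motif, "A")
  expect_equal(got$repeats, 13L)
  expect_equal(got$size, 13L)
  expect_equal(got$start, 3L)
  expect_equal(got$ssr, "(A)13")

  # 9 repeats under a 10-repeat threshold: nothing
  expect_equal(nrow(find_ssrs(paste0("CC", strrep("A", 9), "GG"), strict)),
               0L)

  # six AT units meet the 2/6 dinucleotide threshold: one 12 bp record
  got <- find_ssrs(paste0("GC", strrep("AT", 6), "GC"), strict)
  expect_equal(nrow(got), 1L)
  expect_equal(got$unit_size, 2L)
  expect_equal(got$size, 12L)
})

test_that("runs are attributed to their smallest repeating unit", {
  strict <- ssr_preset("strict")
  # 12 bp of AT is one dinucleotide SSR, not six mononucleotide pairs
  got <- find_ssrs(paste0("G", strrep("AT", 6), "G"), strict)
  expect_equal(got$motif, "AT")
  # a poly-A run never reports as (AA)n
  got <- find_ssrs(paste0("C", strrep("A", 12), "C"), strict)
  expect_equal(got$motif, "A")
  expect_equal(got$unit_size, 1L)
})

test_that("scanner equals the regex oracle on random sequences, all presets", {
  withr::local_seed(601)
  for (preset_name in c("strict", "melotto_modified", "relaxed")) {
    preset <- ssr_preset(preset_name)
    for (rep in 1:3) {
      s <- random_seq(10000)
      # salt the sequence with some genuine repeats
      sv <- strsplit(s, "")[[1]]
      sv[3000:3014] <- rep("T", 15)
      sv[6000:6011] <- rep(c("A", "G"), 6)
      sv[8000:8014] <- rep(c("C", "A", "T"), 5)
      s <- paste(sv, collapse = "")
      got <- find_ssrs(s, preset)
      exp <- oracle_find_ssrs(s, preset$thresholds)
      expect_equal(got[, c("motif", "unit_size", "repeats", "start", "end")],
                   exp, info = paste(preset_name, rep))
    }
  }
})

test_that("relaxing a threshold never reduces the number of SSRs", {
  withr::local_seed(602)
  strict <- ssr_preset("strict")
  for (rep in 1:3) {
    s <- random_seq(10000)
    n_strict <- nrow(find_ssrs(s, strict))
    n_mel <- nrow(find_ssrs(s, ssr_preset("melotto_modified")))
    n_rel <- nrow(find_ssrs(s, ssr_preset("relaxed")))
    # melotto and relaxed both relax every strict threshold
    expect_gte(n_mel, n_strict)
    expect_gte(n_rel, n_strict)
    # single-threshold relaxation
    th <- strict$thresholds
    th[1] <- 8L
    expect_gte(nrow(find_ssrs(s, ssr_preset(thresholds = th))), n_strict)
  }
})

test_that("compound joining matches the published formations", {
  # (T)10 ctctccta (T)10: two constituents, 28 bp span
  s <- paste0("GCGC", strrep("T", 10), "CTCTCCTA", strrep("T", 10), "GCGC")
  rec <- join_compounds(find_ssrs(s, ssr_preset("strict")))
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$compound_id == "C1"))
  comp <- attr(rec, "compounds")
  expect_equal(comp$n, 2L)
  expect_equal(comp$span, 28L)

  # (A)10 <45 bp> (A)10 with max_gap 100: compound of span 65
  withr::local_seed(603)
  gap <- gsub("A", "C", random_seq(45))
  s <- paste0("GC", strrep("A", 10), gap, strrep("A", 10), "GC")
  rec <- join_compounds(find_ssrs(s, ssr_preset("strict")))
  expect_equal(attr(rec, "compounds")$span, 65L)

  # two SSRs 200 bp apart stay simple (cube-free spacer carries no SSR)
  s <- paste0(strrep("A", 10), thue_morse_seq(200), strrep("A", 10))
  rec <- join_compounds(find_ssrs(s, ssr_preset("strict")))
  expect_equal(nrow(rec), 2L)
  expect_true(all(is.na(rec$compound_id)))
})

test_that("motif classes merge rotations and reverse complements", {
  recs <- data.frame(motif = c("A", "T", "G", "AT", "TA"),
                     unit_size = c(1, 1, 1, 2, 2),
                     class = plastcompare:::motif_class(
                       c("A", "T", "G", "AT", "TA")))
  expect_equal(recs$class[1], "A/T")
  expect_equal(recs$class[2], "A/T")
  expect_equal(recs$class[3], "C/G")
  expect_equal(recs$class[4], recs$class[5])
  cls <- classify_motifs(recs)
  expect_equal(cls$by_class$n[cls$by_class$class == "A/T"], 2L)
  expect_equal(cls$by_class$n[cls$by_class$class == "C/G"], 1L)
  empty <- classify_motifs(recs[0, ])
  expect_equal(nrow(empty$by_class), 0L)
})

test_that("published SSR layout is recovered from a synthetic reconstruction", {
  # plant the published Badila SSR complement into a background free of
  # competing repeats, scan under the strict preset, and expect all 30
  # back with their exact printed coordinates
  pub <- published_ssr_loci("officinarum")
  # cube-free C/G background: no tandem run reaches a strict threshold
  s <- thue_morse_seq(90000L)
  planted <- plant_ssrs(s, pub[, c("motif", "repeats", "start")])
  got <- find_ssrs(planted$sequence, ssr_preset("strict"))
  expect_equal(nrow(got), 30L)
  expect_equal(got$start, sort(pub$start))
  expect_equal(got$end, pub$end[order(pub$start)])
  rec <- join_compounds(got)
  comp <- attr(rec, "compounds")
  expect_equal(nrow(comp), 1L)      # the single published compound
  expect_equal(comp$span, 28L)
  cls <- classify_motifs(got)
  expect_equal(cls$by_class$n[cls$by_class$class == "A/T"], 29L)
  expect_equal(cls$by_class$n[cls$by_class$class == "C/G"], 1L)
})
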