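# sliding-window Pi, hotspot calling, K2P distance, NG86 Ka/Ks

test_that("sliding Pi: identical pair is all-zero; window arithmetic holds", {
  withr::local_seed(201)
  s <- strsplit(random_seq(1000), "")[[1]]
  tr <- sliding_pi(list(a = s, b = s), window = 600, step = 200)
  expect_equal(tr$start, c(1L, 201L, 401L, 601L, 801L))
  expect_false(any(tr$partial[1:3]))
  expect_true(all(tr$partial[4:5]))
  expect_true(all(tr$pi == 0))

  # exactly 3 mismatches in a full 600 bp window: pi = 3/600 = 0.005
  b <- s
  b[c(10, 100, 500)] <- vapply(b[c(10, 100, 500)], function(x) {
    setdiff(c("A", "C", "G", "T"), x)[1]
  }, character(1))
  tr <- sliding_pi(list(a = s, b = b), window = 600, step = 200)
  expect_equal(tr$pi[1], 0.005)
  expect_equal(tr$valid_sites[1], 600L)
})

test_that("gap and N columns are excluded from numerator and denominator", {
  a <- c("A", "C", "-", "G", "N", "T", "A")
  b <- c("A", "G", "T", "-", "A", "T", "C")
  tr <- sliding_pi(list(a = a, b = b), window = 6, step = 6)
  # A-positions: A C G N T A -> valid: A/A, C/G, T/T, A/C (G/- and N/A out)
  expect_equal(tr$valid_sites[1], 4L)
  expect_equal(tr$differences[1], 2L)
  expect_equal(tr$pi[1], 0.5)
  # a window with zero valid sites reports NA, not 0
  tr2 <- sliding_pi(list(a = c("A", "C"), b = c("N", "-")),
                    window = 2, step = 1)
  expect_true(is.na(tr2$pi[1]))
})

test_that("sliding Pi equals the naive per-site oracle on random gapped alignments", {
  withr::local_seed(202)
  for (rep in 1:4) {
    n <- 900
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- a
    mut <- sample(n, 25)
    b[mut] <- sample(c("A", "C", "G", "T", "N", "-"), 25, replace = TRUE)
    a[sample(n, 5)] <- "-"
    got <- sliding_pi(list(a = a, b = b), window = 300, step = 100)
    exp <- oracle_sliding_pi(a, b, window = 300, step = 100)
    expect_equal(got$start, exp$start)
    expect_equal(got$valid_sites, exp$valid_sites)
    expect_equal(got$pi, exp$pi)
  }
})

test_that("hotspot calling is strict and merges adjacent windows", {
  tr <- data.frame(start = c(1, 201, 401, 601, 801),
                   end = c(600, 800, 1000, 1200, 1400),
                   valid_sites = 600, differences = 0,
                   pi = c(0, 0.015, 0.007, 0.006, 0), partial = FALSE)
  h <- detect_hotspots(tr, 0.006)
  expect_equal(nrow(h), 1L)           # pi == 0.006 not flagged (strict)
  expect_equal(h$region_start, 201)
  expect_equal(h$region_end, 1000)    # adjacent hot windows merged
  expect_equal(h$n_windows, 2L)
  expect_equal(h$max_pi, 0.015)
  tr$pi <- 0
  expect_equal(nrow(detect_hotspots(tr, 0.006)), 0L)
})

test_that("K2P closed form and saturation guard", {
  withr::local_seed(203)
  s <- random_seq(500)
  same <- k2p_distance(s, s)
  expect_equal(same$d, 0)
  expect_equal(same$P, 0)
  expect_equal(same$Q, 0)

  # 100 valid sites, one transition: d = -1/2 log(0.98)
  a <- paste(rep("A", 50), collapse = "")
  b <- a
  av <- strsplit(paste0(a, paste(rep("C", 50), collapse = "")), "")[[1]]
  bv <- av
  bv[1] <- "G"
  got <- k2p_distance(list(a = av, b = bv))
  expect_equal(got$P, 0.01)
  expect_equal(got$Q, 0)
  expect_equal(got$d, -0.5 * log(0.98), tolerance = 1e-12)

  # constructed (P, Q) = (0.25, 0.25) stays finite
  a4 <- c("A", "A", "C", "A")       # P: A->G; Q: C->A; 4 sites
  b4 <- c("G", "A", "A", "A")
  got <- k2p_distance(list(a = a4, b = b4))
  expect_equal(got$P, 0.25)
  expect_equal(got$Q, 0.25)
  expect_equal(got$d,
               -0.5 * log(1 - 2 * 0.25 - 0.25) - 0.25 * log(1 - 2 * 0.25),
               tolerance = 1e-12)

  # saturation: P + Q too large
  expect_error(k2p_distance(list(a = c("A", "C"), b = c("G", "T"))),
               "saturated")
})

test_that("K2P agrees with ape's K80 distance and dominates the p-distance", {
  skip_if_not_installed("ape")
  withr::local_seed(204)
  for (rep in 1:5) {
    n <- 600
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- a
    mut <- sample(n, 30)
    b[mut] <- vapply(b[mut], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    got <- k2p_distance(list(a = a, b = b))
    bin <- ape::as.DNAbin(matrix(tolower(c(a, b)), nrow = 2, byrow = TRUE))
    expect_equal(got$d, as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-10)
    expect_gte(got$d, got$P + got$Q)
  }
})

test_that("NG86 agrees with the pathway-enumeration oracle on all codon pairs", {
  skip_if_not_installed("seqinr")
  gc <- Biostrings::GENETIC_CODE
  nonstop <- names(gc)[gc != "*"]
  pairs <- expand.grid(a = nonstop, b = nonstop, stringsAsFactors = FALSE)
  expect_equal(nrow(pairs), 3721L)
  got <- t(vapply(seq_len(nrow(pairs)), function(i) {
    cmp <- plastcompare:::ng86_components(
      matrix(c(pairs$a[i], pairs$b[i]), ncol = 2))
    c(cmp$S, cmp$N, cmp$Sd, cmp$Nd)
  }, numeric(4)))
  exp <- t(vapply(seq_len(nrow(pairs)), function(i) {
    o <- oracle_ng86(pairs$a[i], pairs$b[i])
    c(o$S, o$N, o$Sd, o$Nd)
  }, numeric(4)))
  expect_equal(got, exp, tolerance = 1e-12)
})

test_that("NG86 worked examples: single-codon substitutions", {
  # GGC vs GGT (Gly/Gly): one synonymous difference at a fully synonymous
  # site; with S = 1 the JC correction saturates for the isolated pair
  expect_error(ng86_kaks(matrix(c("GGC", "GGT"), ncol = 2)), "saturated")
  # diluted among identical codons the change is pure Ks
  a <- paste(c("GGC", rep("ATT", 19)), collapse = "")
  b <- paste(c("GGT", rep("ATT", 19)), collapse = "")
  kk <- ng86_kaks(a, b)
  expect_equal(kk$ka, 0)
  expect_gt(kk$ks, 0)
  expect_equal(kk$ka_ks, 0)
  expect_equal(classify_selection(kk$ka, kk$ks), "strong_purifying")

  # TTT vs TTA (Phe -> Leu): nonsynonymous only, ks = 0, ratio undefined
  kk <- ng86_kaks(matrix(c("TTT", "TTA"), ncol = 2))
  expect_gt(kk$ka, 0)
  expect_equal(kk$ks, 0)
  expect_true(is.na(kk$ka_ks))

  # identical sequences
  kk <- ng86_kaks("ATGGCT", "ATGGCT")
  expect_equal(kk$ka, 0)
  expect_equal(kk$ks, 0)
  expect_true(is.na(kk$ka_ks))

  # internal stop codon is an integrity error
  expect_error(ng86_kaks("ATGTAAGCT", "ATGTAAGCT"), "stop")
})

test_that("Pi and K2P are invariant under strand", {
  withr::local_seed(205)
  pair <- generate_pair(synthetic_config(seed = 205))
  cds <- pair$truth$cds_a
  a <- cds[[1]]
  av <- strsplit(a, "")[[1]]
  idx <- seq(10, 60, by = 7)
  av[idx] <- vapply(av[idx], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1)
  }, character(1))
  b <- paste(av, collapse = "")
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  fw <- sliding_pi(list(a = strsplit(a, "")[[1]], b = strsplit(b, "")[[1]]),
                   window = nchar(a), step = nchar(a))
  rv <- sliding_pi(list(a = strsplit(rc(a), "")[[1]],
                        b = strsplit(rc(b), "")[[1]]),
                   window = nchar(a), step = nchar(a))
  expect_equal(fw$pi[1], rv$pi[1])
  k_fw <- k2p_distance(a, b)
  k_rv <- k2p_distance(rc(a), rc(b))
  expect_equal(k_fw$d, k_rv$d)
})

test_that("selection classes follow the Ka/Ks criteria", {
  expect_equal(classify_selection(0.002, 0.001), "positive")
  expect_equal(classify_selection(0.001, 0.001), "neutral")
  expect_equal(classify_selection(0.0005, 0.001), "purifying")
  expect_equal(classify_selection(0, 0.003), "strong_purifying")
  expect_equal(classify_selection(0.001, 0), "undefined")
  expect_error(classify_selection(-1, 0.1), "non-negative")
})
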