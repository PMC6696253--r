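# FASTA / annotation reading, normalization, and CDS extraction

test_that("FASTA round trip normalizes case and RNA alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">one", "acgtacgtua", ">two desc", "GGGCCC"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[["one"]]$sequence, "ACGTACGTTA")
  expect_equal(recs[["one"]]$length, 10L)
  expect_equal(recs[["two"]]$id, "two")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, out)
  again <- read_fasta(out)
  expect_equal(lapply(again, `[[`, "sequence"),
               lapply(recs, `[[`, "sequence"))
})

test_that("non-nucleotide characters are a format error", {
  expect_error(genome_record("bad", "ACGTJ"), "non-IUPAC")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("GFF3 annotations round-trip with exact coordinates and strands", {
  feats <- list(
    gene_feature("psbA", "CDS", "-", cbind(start = 101L, end = 200L)),
    gene_feature("ycf3", "CDS", "+",
                 cbind(start = c(300L, 451L), end = c(380L, 600L))),
    gene_feature("rps12", "CDS", "+", cbind(start = 700L, end = 801L),
                 trans_spliced = TRUE, partial = TRUE),
    gene_feature("ndhB", "CDS", "+", cbind(start = 900L, end = 1001L),
                 copy_index = 2L)
  )
  ann <- annotation_set("toy", feats)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_annotations(ann, f)
  back <- read_annotations(f, "gff3")
  expect_equal(back$genome_id, "toy")
  expect_length(back$features, 4L)
  key <- function(a) {
    vapply(a$features, function(x) paste0(x$gene_name, "#", x$copy_index),
           character(1))
  }
  reord <- match(key(ann), key(back))
  for (i in seq_along(feats)) {
    got <- back$features[[reord[i]]]
    expect_equal(got$exons, feats[[i]]$exons, info = feats[[i]]$gene_name)
    expect_equal(got$strand, feats[[i]]$strand)
    expect_equal(got$trans_spliced, feats[[i]]$trans_spliced)
  }
  # two CDS segments sharing a parent collapse into one two-exon feature
  y <- back$features[[reord[2]]]
  expect_equal(nrow(y$exons), 2L)
})

test_that("annotation errors: bounds and strand symbols", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("g", ".", "CDS", "10", "5000", ".", "+", "0",
                     "ID=x;Parent=gene-x;gene=x", sep = "\t")), f)
  expect_error(read_annotations(f, "gff3", genome_length = 1000L,
                                circular = FALSE), "bounds")
  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("g", ".", "CDS", "10", "50", ".", "?", "0",
                     "ID=x;Parent=gene-x;gene=x", sep = "\t")), f2)
  expect_error(read_annotations(f2, "gff3"), "strand")
})

test_that("extract_cds splices, reverse-complements and wraps the origin", {
  g <- genome_record("toy", "ATGAAATAATTACATTTTCCGGCCGG", circular = TRUE)
  ann <- annotation_set("toy", list(
    gene_feature("plus1", "CDS", "+", cbind(1L, 9L)),
    gene_feature("minus1", "CDS", "-", cbind(10L, 18L))
  ))
  cds <- extract_cds(g, ann)
  expect_equal(unname(cds["plus1"]), "ATGAAATAA")
  expect_equal(unname(cds["minus1"]), "AAAATGTAA")

  # trans-spliced features are dropped when skip_trans_spliced = TRUE
  ann2 <- annotation_set("toy", list(
    gene_feature("plus1", "CDS", "+", cbind(1L, 9L)),
    gene_feature("rps12", "CDS", "+", cbind(10L, 18L), trans_spliced = TRUE)
  ))
  expect_named(extract_cds(g, ann2, skip_trans_spliced = TRUE), "plus1")
  expect_setequal(names(extract_cds(g, ann2, skip_trans_spliced = FALSE)),
                  c("plus1", "rps12"))

  # origin-spanning exon on a circular genome: end > length wraps around
  ann3 <- annotation_set("toy", list(
    gene_feature("wrap", "CDS", "+", cbind(25L, 30L))))
  expect_equal(unname(extract_cds(g, ann3)["wrap"]),
               paste0("GG", "ATGA"))
  # same coordinates on a linear record are an error
  glin <- genome_record("lin", g$sequence, circular = FALSE)
  expect_error(extract_cds(glin, ann3), "linear")
})

test_that("CDS length not a multiple of 3 is an integrity error", {
  g <- genome_record("toy", "ATGAAATAAT", circular = FALSE)
  ann <- annotation_set("toy", list(
    gene_feature("bad", "CDS", "+", cbind(1L, 10L))))
  expect_error(extract_cds(g, ann), "multiple of 3")
  ann_ok <- annotation_set("toy", list(
    gene_feature("bad", "CDS", "+", cbind(1L, 10L), partial = TRUE)))
  expect_silent(extract_cds(g, ann_ok))
})

test_that("extract_cds recovers exactly the generator's planted coding strings", {
  pair <- generate_pair(synthetic_config(seed = 11))
  cds <- extract_cds(pair$genome_a, pair$annot_a, skip_trans_spliced = FALSE)
  truth <- pair$truth$cds_a
  for (nm in names(truth)) {
    expect_equal(unname(cds[nm]), unname(truth[nm]), info = nm)
  }
  # the IR-duplicated copy carries the same coding sequence
  expect_equal(unname(cds["irdG.2"]), unname(truth["irdG"]))
})
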