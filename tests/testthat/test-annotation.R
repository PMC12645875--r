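# Annotation reading, intron derivation, snoRNA placement, reference
# database construction, and coordinate projection.

test_that("introns are the exact gaps between adjacent exons", {
  ann <- tiny_annotation()
  host <- ann$transcripts[["HOSTA"]]
  expect_equal(nrow(host$exons_local), 3)
  expect_equal(unname(host$introns_local[1, ]), c(101L, 300L))
  expect_equal(unname(host$introns_local[2, ]), c(401L, 600L))
  # exons union + introns union tile the gene span without overlap
  covered <- sort(c(
    unlist(apply(host$exons_local, 1, function(x) x[1]:x[2])),
    unlist(apply(host$introns_local, 1, function(x) x[1]:x[2]))))
  expect_identical(covered, seq_len(host$span_len))
})

test_that("a snoRNA contained in a host intron gets that placement", {
  ann <- tiny_annotation()
  plc <- ann$sno_placements
  expect_equal(nrow(plc), 1)
  expect_equal(plc$snorna_id, "SNOA")
  expect_equal(plc$host_tx, "HOSTA")
  expect_equal(plc$host_intron, 1L)
  expect_equal(c(plc$sno_local_start, plc$sno_local_end), c(121L, 200L))
})

test_that("minus-strand introns come out in transcript orientation", {
  ann <- tiny_annotation()
  mrev <- ann$transcripts[["MREV"]]
  # genomic exons 5001-5100 / 5201-5300 / 5401-5500 on '-':
  # transcript-local exons are 1-100 (genomic 5401-5500), 201-300, 401-500
  expect_equal(unname(mrev$exons_local[1, ]), c(1L, 100L))
  expect_equal(unname(mrev$introns_local[1, ]), c(101L, 200L))
  # hand-computed: local 1 is genomic 5500; local 500 is genomic 5001
  g <- tx_to_genome(c(1, 1), mrev)
  expect_equal(g$start, 5500)
})

test_that("a missing FASTA sequence is a hard error", {
  f <- tiny_annotation_files()
  fa2 <- withr::local_tempfile(fileext = ".fa")
  lines <- readLines(f$fasta)
  writeLines(lines[1:(length(lines) - 2)], fa2)   # drop MREV
  expect_error(read_annotation(f$gtf, fa2, f$sites), "missing sequence")
})

test_that("reference db extends snoRNAs by the flank and masks the host", {
  ann <- tiny_annotation()
  db <- build_reference_db(ann, flank = 20)
  # snoRNA of length 80 mid-intron, flank 20 -> 120 nt entry
  expect_equal(nchar(db$sequences[["SNOA"]]), 120)
  meta <- db$meta[db$meta$id == "SNOA", ]
  expect_equal(c(meta$ext_left, meta$ext_right), c(20L, 20L))
  # host carries exactly sno_len + 2*flank N's at the placement
  host <- db$sequences[["HOSTA"]]
  expect_equal(nchar(gsub("[^N]", "", host)), 120)
  expect_equal(substring(host, 101, 101 + 119), strrep("N", 120))
  # the entry equals the unmasked host context around the snoRNA
  expect_equal(db$sequences[["SNOA"]],
               substring(ann$sequences[["HOSTA"]], 101, 220))
})

test_that("flank 0 keeps the annotated snoRNA span unchanged", {
  ann <- tiny_annotation()
  db <- build_reference_db(ann, flank = 0)
  expect_equal(db$sequences[["SNOA"]], ann$sequences[["SNOA"]])
})

test_that("transcript intervals split at exon junctions when projected", {
  ann <- tiny_annotation()
  host <- ann$transcripts[["HOSTA"]]
  # spliced positions 95..105 cross the exon1/exon2 junction (each exon 100)
  g <- tx_to_genome(c(95, 105), host)
  expect_equal(nrow(g), 2)
  expect_equal(c(g$start[1], g$end[1]), c(1095, 1100))
  expect_equal(c(g$start[2], g$end[2]), c(1301, 1305))
  # single-exon transcript: plain offset shift
  rrn <- ann$transcripts[["RRN"]]
  g1 <- tx_to_genome(c(10, 20), rrn)
  expect_equal(c(g1$start, g1$end), c(3010, 3020))
  expect_error(tx_to_genome(c(0, 5), rrn), "range")
  expect_error(tx_to_genome(c(1, 501), rrn), "range")
})

test_that("genome projection round-trips on a minus-strand transcript", {
  ann <- tiny_annotation()
  mrev <- ann$transcripts[["MREV"]]
  set.seed(2024)
  for (k in 1:200) {
    s <- sample(1:300, 1); e <- min(300, s + sample(0:80, 1))
    g <- tx_to_genome(c(s, e), mrev)
    back <- genome_to_tx(g, mrev)
    expect_equal(unname(back), c(s, e))
  }
})

test_that("known-site table validation catches bad positions and duplicates", {
  f <- tiny_annotation_files()
  bad <- withr::local_tempfile()
  writeLines(c("target_id\tposition\tguide_family\tbox\tsource",
               "RRN\t9999\tSNOA\tD\ttest"), bad)
  expect_error(read_annotation(f$gtf, f$fasta, bad), "bounds")
  dup <- withr::local_tempfile()
  writeLines(c("target_id\tposition\tguide_family\tbox\tsource",
               "RRN\t100\tSNOA\tD\ttest",
               "RRN\t100\tSNOA\tD\tother"), dup)
  expect_error(read_annotation(f$gtf, f$fasta, dup), "duplicate")
})

test_that("BED export writes half-open six-column records", {
  ann <- tiny_annotation()
  g <- tx_to_genome(c(95, 105), ann$transcripts[["HOSTA"]])
  f <- withr::local_tempfile(fileext = ".bed")
  export_bed(g, f, names = "frag1")
  bed <- utils::read.delim(f, header = FALSE)
  expect_equal(nrow(bed), 2)
  expect_equal(bed$V2, c(1094, 1300))   # 0-based starts
  expect_equal(bed$V3, c(1100, 1305))
})
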