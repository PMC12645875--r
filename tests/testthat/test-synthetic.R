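# The synthetic-data generator: determinism, planted ground truth, and
# its verification guarantees.

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 5, n_interactions = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- generate_reference(cfg, dir = d1)
  r2 <- generate_reference(cfg, dir = d2)
  for (f in c("reference.gtf", "reference.fa", "sites.tsv", "boxes.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  c1 <- generate_chimeras(cfg, r1, dir = d1)
  c2 <- generate_chimeras(cfg, r2, dir = d2)
  expect_identical(readLines(file.path(d1, "chimeras.hyb")),
                   readLines(file.path(d2, "chimeras.hyb")))
  s1 <- generate_single_reads(cfg, r1)
  s2 <- generate_single_reads(cfg, r2)
  expect_identical(s1$single_hits, s2$single_hits)
})

test_that("reference files round-trip through the package readers", {
  b <- shared_synth()
  ann <- read_annotation(b$ref$files$gtf, b$ref$files$fasta,
                         b$ref$files$sites)
  expect_setequal(names(ann$transcripts), names(b$ref$annotation$transcripts))
  # placements recovered identically (snoRNA mid host intron 1)
  p1 <- ann$sno_placements[order(ann$sno_placements$snorna_id), ]
  p2 <- b$ref$annotation$sno_placements[
    order(b$ref$annotation$sno_placements$snorna_id), ]
  rownames(p1) <- rownames(p2) <- NULL
  expect_equal(p1, p2)
  expect_true(all(p1$sno_local_start == 401L, p1$sno_local_end == 462L))
  # sequences identical after the FASTA round trip
  expect_identical(ann$sequences[names(b$ref$annotation$sequences)],
                   b$ref$annotation$sequences)
})

test_that("planted site positions fall inside the target and match truth", {
  b <- shared_synth()
  ks <- b$ref$annotation$known_sites
  len <- nchar(b$ref$annotation$sequences[["RNA45S_SYN"]])
  expect_true(all(ks$position >= 1 & ks$position <= len))
  strict <- b$chim$truth[b$chim$truth$class == "methylation_strict", ]
  expect_true(all(strict$site_pos %in% ks$position))
})

test_that("every planted guide satisfies the naive strict rule", {
  b <- shared_synth()
  plan <- b$ref$plan
  db <- b$ref$db
  strict <- plan[plan$class == "methylation_strict", ]
  expect_gt(nrow(strict), 0)
  for (r in seq_len(nrow(strict))) {
    sno <- strict$sno_id[r]
    f1 <- substring(db$sequences[[sno]], strict$sno_start[r],
                    strict$sno_end[r])
    f2 <- substring(db$sequences[[strict$target_id[r]]],
                    strict$t_start[r], strict$t_end[r])
    d <- predict_duplex(f1, f2)
    g <- guide_geometry(d, c(strict$sno_start[r], strict$sno_end[r]),
                        c(strict$t_start[r], strict$t_end[r]),
                        b$ref$boxes[[sno]], "D")
    expect_identical(
      naive_guide_call(g$offsets$exact, g$offsets$paired, g$box_exact,
                       g$n_pairs_total),
      "strict")
    expect_equal(g$predicted_target_pos, strict$site_pos[r])
    expect_true(energy_filter(d))
  }
})

test_that("duplicate_rate 0 yields no reproducible clusters", {
  cfg <- synthetic_config(seed = 6, n_interactions = 7, duplicate_rate = 0)
  ref <- generate_reference(cfg)
  chim <- generate_chimeras(cfg, ref)
  expect_true(all(chim$truth$support == 1))
  cl <- cluster_reproducible(chim$chimeras)
  expect_equal(sum(cl$reproducible), 0)
  expect_true(all(chim$truth$expected_disposition %in%
                    c("dropped_singleton", "intramolecular",
                      "mismap_removed")))
})

test_that("mismap decoy chimeras are removed at default thresholds", {
  b <- shared_synth()
  decoy_reads <- b$chim$truth$read_id[b$chim$truth$class == "mismap_decoy"]
  expect_gt(length(decoy_reads), 0)
  recs <- b$chim$chimeras[b$chim$chimeras$read_id %in% decoy_reads, ]
  decoys <- b$ref$db$sequences[c("U3_SYN", "RNA45S_SYN")]
  out <- filter_mismap(recs, decoys, b$ref$annotation)
  expect_setequal(out$removed$read_id, decoy_reads)
})

test_that("fragment lengths match the configured distribution", {
  b <- shared_synth()
  ch <- b$chim$chimeras
  l1 <- ch$r1_end - ch$r1_begin + 1
  # snoRNA fragments sit in the 20-45 nt range typical of the protocol
  expect_true(all(l1 >= 15 & l1 <= 50))
})

test_that("single reads: same seed identical; enrichment peaks at zero", {
  b <- shared_synth()
  cfg <- b$cfg
  sr <- generate_single_reads(cfg, b$ref)
  out <- hybrid_vs_single_stats(sr$hybrid_starts, sr$single_hits,
                                abundance = sr$abundance,
                                window = 100L)
  prof <- out$metaprofile
  bins <- tapply(prof, abs(as.integer(names(prof))) %/% 25, sum)
  expect_equal(names(which.max(bins)), "0")
  # enrichment 0 -> approximately flat profile
  cfg0 <- synthetic_config(seed = 12, n_interactions = 7,
                           single_enrichment = 0)
  ref0 <- generate_reference(cfg0)
  sr0 <- generate_single_reads(cfg0, ref0)
  out0 <- hybrid_vs_single_stats(sr0$hybrid_starts, sr0$single_hits,
                                 window = 100L)
  p0 <- out0$metaprofile
  b0 <- tapply(p0, abs(as.integer(names(p0))) %/% 25, sum)
  expect_lt(max(b0[1:4]) / max(1, min(b0[1:4])), 3)
})
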