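# The decision tree: strict/weak guide criteria, ancillary, blocking,
# and full-precedence classification.

canon <- function() {
  # canonical guide: offsets 1..12 exact, box unpaired, 12 total pairs
  make_geom(exact16 = c(rep(TRUE, 12), rep(FALSE, 4)))
}

test_that("strict criterion holds on the canonical guide and each clause can fail", {
  cfg <- classifier_config()
  expect_true(check_strict(canon(), cfg)$ok)

  # offset-5 pair replaced by G-U: clause 1 fails
  g <- canon()
  g$offsets$exact[5] <- FALSE            # still paired (wobble)
  r <- check_strict(g, cfg)
  expect_false(r$ok)
  expect_false(r$evidence[["offset5_exact"]])

  # fewer than 12 total pairs
  g <- canon(); g$n_pairs_total <- 11L
  r <- check_strict(g, cfg)
  expect_false(r$ok)
  expect_false(r$evidence[["min_total_pairs"]])

  # no exact pair among offsets 2-4
  g <- make_geom(exact16 = c(FALSE, FALSE, FALSE, FALSE, rep(TRUE, 11), FALSE),
                 paired16 = rep(TRUE, 16), n_total = 12L)
  r <- check_strict(g, cfg)
  expect_false(r$evidence[["seed_2_4_exact"]])

  # all four box nucleotides exactly paired: clause 3 fails
  g <- canon(); g$box_exact <- rep(TRUE, 4); g$n_pairs_total <- 16L
  r <- check_strict(g, cfg)
  expect_false(r$ok)
  expect_false(r$evidence[["box_not_fully_exact"]])
})

test_that("the 11-in-16 stretch with one internal mismatch rescues strict", {
  cfg <- classifier_config()
  # exact at offsets 2..12 except a single mismatch at 7: no 8-run, but an
  # 11-window (2..12) with exactly one non-exact position
  ex <- rep(FALSE, 16)
  ex[2:12] <- TRUE; ex[7] <- FALSE
  g <- make_geom(exact16 = ex, paired16 = ex | (1:16 == 7), n_total = 12L)
  r <- check_strict(g, cfg)
  expect_true(r$ok)
  expect_true(r$evidence[["stretch"]])
  # two mismatches in every 11-window: strict fails
  ex2 <- ex; ex2[3] <- FALSE
  g2 <- make_geom(exact16 = ex2, paired16 = ex2 | (1:16 %in% c(3, 7)),
                  n_total = 12L)
  expect_false(check_strict(g2, cfg)$ok)
})

test_that("the 8-run must lie entirely within offsets 1..14", {
  cfg <- classifier_config()
  # offsets 2 and 5 exact so clauses 1-2 hold in both cases; the 8-run at
  # 8..15 crosses the window edge and no 11-window has <= 1 mismatch
  ex <- rep(FALSE, 16); ex[c(2, 5, 8:15)] <- TRUE
  g <- make_geom(exact16 = ex, n_total = 12L)
  expect_false(check_strict(g, cfg)$ok)
  # the same run shifted to 7..14 lies inside the window
  ex <- rep(FALSE, 16); ex[c(2, 5, 7:14)] <- TRUE
  g <- make_geom(exact16 = ex, n_total = 12L)
  expect_true(check_strict(g, cfg)$ok)
})

test_that("weak criterion: offset-5 paired (G-U allowed) after strict fails", {
  g <- make_geom(exact16 = rep(FALSE, 16),
                 paired16 = (1:16) == 5, n_total = 5L)
  expect_true(check_weak(g))
  g2 <- make_geom(exact16 = rep(FALSE, 16), paired16 = rep(FALSE, 16),
                  n_total = 0L)
  expect_false(check_weak(g2))
})

test_that("ancillary distance boundaries: 0 (overlap) and 100/101", {
  sites <- data.frame(target_id = "RR", position = 180L,
                      guide_family = "F1", box = "D", source = "t")
  cfg <- classifier_config()
  expect_true(check_ancillary(c(100, 130), "RR", "F1", sites, cfg)$ok)
  # interval covering the site: overlap, not ancillary
  expect_false(check_ancillary(c(150, 200), "RR", "F1", sites, cfg)$ok)
  # exactly 100 away passes, 101 fails
  expect_true(check_ancillary(c(60, 80), "RR", "F1", sites, cfg)$ok)
  expect_false(check_ancillary(c(60, 79), "RR", "F1", sites, cfg)$ok)
  # other family's site does not count
  expect_false(check_ancillary(c(100, 130), "RR", "F2", sites, cfg)$ok)
})

test_that("blocking flips between 21 and 22 Watson-Crick pairs", {
  cfg <- classifier_config()
  sites <- data.frame(target_id = "RR", position = 112L,
                      guide_family = "OTHER", box = "D", source = "t")
  # k pairs cover target positions 100..100+k-1, all within 112 +/- 17
  expect_false(check_blocking(gc_duplex(21), c(100, 124), "RR", "F1",
                              sites, cfg = cfg)$ok)
  r <- check_blocking(gc_duplex(22), c(100, 124), "RR", "F1", sites,
                      cfg = cfg)
  expect_true(r$ok)
  expect_equal(r$site, 112L)
})

test_that("blocking is vetoed by an own-guided site closer than 20 nt", {
  cfg <- classifier_config()
  sites <- data.frame(target_id = rep("RR", 2), position = c(112L, 127L),
                      guide_family = c("OTHER", "F1"),
                      box = "D", source = "t")
  # F1 guides a site 15 nt from the blocked site -> vetoed
  expect_false(check_blocking(gc_duplex(22), c(100, 124), "RR", "F1",
                              sites, cfg = cfg)$ok)
  # at exactly 20 nt separation the veto no longer applies
  sites$position[2] <- 132L
  expect_true(check_blocking(gc_duplex(22), c(100, 124), "RR", "F1",
                             sites, cfg = cfg)$ok)
})

test_that("classification precedence: overlap with an own site beats blocking", {
  # duplex pairing the snoRNA accessory region (not the guide offsets);
  # target interval covers a site guided by this snoRNA
  sno <- paste0(strrep("A", 11), "GGAUCCGAUGCUAG", strrep("A", 16),
                "AGCUGGAUCCAG", "CUGA", "AAA")   # box D at 54
  anti <- revcomp_rna("GGAUCCGAUGCUAG")
  target <- paste0(strrep("A", 8), anti, strrep("A", 8))
  d <- predict_duplex(substr(sno, 10, 30), target)
  boxes <- box_annotation("S", boxC_start = 4, boxD_start = 54)
  sites <- data.frame(target_id = "RR", position = 215L,
                      guide_family = "S", box = "D", source = "t")
  call <- classify_interaction(d, sno_frag = c(10, 30),
                               target_frag = c(201, 230), target_id = "RR",
                               target_biotype = "rRNA", family = "S",
                               boxes = boxes, known_sites = sites)
  expect_equal(call$label, "known_site_overlap")
  expect_equal(call$matched_known_site, 215L)
})

test_that("zero-pair duplexes fall through to structural (rRNA) or unclassified", {
  d <- predict_duplex(strrep("A", 30), strrep("A", 30))
  boxes <- box_annotation("S", boxC_start = 4, boxD_start = 25)
  sites <- read_known_sites(NULL)
  call_r <- classify_interaction(d, c(1, 30), c(1, 30), "RR", "rRNA", "S",
                                 boxes, sites)
  expect_equal(call_r$label, "structural")
  call_m <- classify_interaction(d, c(1, 30), c(1, 30), "MR", "mRNA", "S",
                                 boxes, sites)
  expect_equal(call_m$label, "unclassified")
})

test_that("a missing box D annotation yields unclassified with a reason", {
  d <- predict_duplex("ACGU", "ACGU")
  call <- classify_interaction(d, c(1, 4), c(1, 4), "RR", "rRNA", "S",
                               boxes = NULL,
                               known_sites = read_known_sites(NULL))
  expect_equal(call$label, "unclassified")
  expect_match(call$reason, "box")
})

test_that("classifier configuration round-trips and reproduces calls", {
  cfg <- classifier_config(blocking_flank = 15L, ancillary_flank = 80L)
  f <- withr::local_tempfile(fileext = ".json")
  write_classifier_config(cfg, f)
  cfg2 <- read_classifier_config(f)
  expect_identical(cfg, cfg2)
  g <- canon()
  expect_identical(check_strict(g, cfg), check_strict(g, cfg2))
})

test_that("adding an exact pair at an unpaired offset never breaks strict", {
  cfg <- classifier_config()
  set.seed(99)
  for (rep in 1:50) {
    ex <- stats::runif(16) < 0.6
    g <- make_geom(exact16 = ex, n_total = sum(ex) + 6L)
    if (!check_strict(g, cfg)$ok) next
    free <- which(!g$offsets$paired)
    if (!length(free)) next
    k <- sample(free, 1)
    g2 <- g
    g2$offsets$paired[k] <- TRUE; g2$offsets$exact[k] <- TRUE
    g2$n_pairs_total <- g$n_pairs_total + 1L
    expect_true(check_strict(g2, cfg)$ok)
  }
})
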