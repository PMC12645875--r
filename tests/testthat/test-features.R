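# Feature assignment, host relations, branch-point windows, metaprofiles,
# interval tables, and hybrid-vs-single statistics.

test_that("feature assignment: containment, majority, and tie precedence", {
  ann <- tiny_annotation()
  host <- ann$transcripts[["HOSTA"]]
  # HOSTA local: UTR5 1-50, CDS 51-100, intron1 101-300, CDS 301-400,
  # intron2 401-600, CDS 601-650, UTR3 651-700
  expect_equal(assign_feature(c(60, 90), host), "CDS")
  expect_equal(assign_feature(c(10, 40), host), "UTR5")
  expect_equal(assign_feature(c(660, 690), host), "UTR3")
  expect_equal(assign_feature(c(150, 250), host), "intron")
  # 60% intron / 40% CDS -> intron by majority
  expect_equal(assign_feature(c(271, 320), host), "intron")
  # exact 50/50 tie CDS vs intron -> CDS by precedence
  expect_equal(assign_feature(c(291, 310), host), "CDS")
  # no model -> intergenic
  expect_equal(assign_feature(c(1, 10), NULL), "intergenic")
  # noncoding transcript exons
  expect_equal(assign_feature(c(10, 30), ann$transcripts[["RRN"]]),
               "exon_noncoding")
})

test_that("planted fragments recover their feature labels exactly", {
  ann <- tiny_annotation()
  host <- ann$transcripts[["HOSTA"]]
  zones <- list(UTR5 = c(1, 50), CDS = c(51, 100), intron = c(101, 300),
                UTR3 = c(651, 700))
  set.seed(12)
  for (k in 1:100) {
    f <- sample(names(zones), 1)
    z <- zones[[f]]
    s <- sample(z[1]:(z[2] - 5), 1)
    e <- min(z[2], s + sample(3:10, 1))
    expect_equal(assign_feature(c(s, e), host), f, info = sprintf("%s %d-%d", f, s, e))
  }
})

test_that("host relations distinguish cis, trans-within-host, and non-host", {
  ann <- tiny_annotation()
  # SNOA lives in HOSTA intron 1 (local 101-300)
  expect_equal(host_relation("SNOA", "HOSTA", c(250, 290), ann),
               "host_intron_cis")
  expect_equal(host_relation("SNOA", "HOSTA", c(450, 480), ann),
               "same_host_gene_trans")
  expect_equal(host_relation("SNOA", "MREV", c(120, 150), ann), "non_host")
  expect_warning(r <- host_relation("NOPLACE", "HOSTA", c(250, 290), ann),
                 "placement")
  expect_equal(r, "non_host")
})

test_that("branch-point window edge semantics are (F,T,T,F) at 19/20/50/51", {
  intron <- c(101L, 300L)      # 3' end at 300; window 250..280
  got <- vapply(c(19L, 20L, 50L, 51L), function(d) {
    p <- intron[2] - d
    branchpoint_window(c(p, p), intron, window = c(20L, 50L))
  }, logical(1))
  expect_identical(got, c(FALSE, TRUE, TRUE, FALSE))
  # a fragment ending 30 nt upstream overlaps the window
  expect_true(branchpoint_window(c(255, 270), intron))
  # confined to the last 0-19 nt: outside
  expect_false(branchpoint_window(c(281, 300), intron))
})

test_that("metaprofile counts overlapping fragments position-wise", {
  introns <- data.frame(intron_id = "i1", start = 1001L, end = 3000L)
  frags <- data.frame(intron_id = "i1", start = 3000L - 40L, end = 3000L - 25L)
  prof <- intron_metaprofile(frags, introns)
  expect_equal(sum(prof), 16)
  expect_true(all(prof[as.character(-40:-25)] == 1))
  expect_true(all(prof[setdiff(names(prof), as.character(-40:-25))] == 0))
  # empty input -> zero vector; mass equals clipped fragment lengths
  expect_equal(sum(intron_metaprofile(frags[0, ], introns)), 0)
  short <- data.frame(intron_id = "s", start = 2901L, end = 3000L) # 100 nt
  fr2 <- data.frame(intron_id = "s", start = 2801L, end = 2950L)
  expect_equal(sum(intron_metaprofile(fr2, short)), 50)  # clipped suffix
})

test_that("a planted -35 enrichment centre is recovered by the profile argmax", {
  set.seed(500)
  introns <- data.frame(intron_id = "i1", start = 1L, end = 5000L)
  centre <- round(stats::rnorm(500, mean = 5000 - 35, sd = 6))
  frags <- data.frame(intron_id = "i1", start = centre - 5L,
                      end = centre + 5L)
  prof <- intron_metaprofile(frags, introns)
  peak <- as.integer(names(prof)[which.max(prof)])
  expect_gte(peak, -50)
  expect_lte(peak, -20)
  expect_lt(abs(peak - (-35)), 10)
})

test_that("interval overlap and closest tables match a quadratic scan", {
  set.seed(77)
  for (rep in 1:10) {
    a <- data.frame(start = sample(1:500, 25))
    a$end <- a$start + sample(0:30, 25, TRUE)
    b <- data.frame(start = sample(1:500, 15))
    b$end <- b$start + sample(0:10, 15, TRUE)
    got <- interval_overlap_and_closest(a, b)
    # naive O(n*m) oracle
    ov <- list(); cl <- integer(nrow(a)); dist <- integer(nrow(a))
    for (i in seq_len(nrow(a))) {
      best <- NULL
      for (j in seq_len(nrow(b))) {
        if (a$start[i] <= b$end[j] && a$end[i] >= b$start[j]) {
          ov[[length(ov) + 1]] <- c(i, j)
        }
        g <- if (b$start[j] > a$end[i]) b$start[j] - a$end[i]
             else if (b$end[j] < a$start[i]) b$end[j] - a$start[i] else 0L
        if (is.null(best) || abs(g) < abs(best[2]) ||
            (abs(g) == abs(best[2]) && b$start[j] < b$start[best[1]])) {
          best <- c(j, g)
        }
      }
      cl[i] <- best[1]; dist[i] <- best[2]
    }
    ovm <- do.call(rbind, ov)
    expect_equal(nrow(got$overlaps), NROW(ovm))
    if (NROW(ovm)) {
      o1 <- got$overlaps[order(got$overlaps$a, got$overlaps$b), ]
      o2 <- as.data.frame(ovm[order(ovm[, 1], ovm[, 2]), , drop = FALSE])
      expect_equal(unname(as.matrix(o1)), unname(as.matrix(o2)))
    }
    expect_equal(got$closest$b, cl)
    expect_equal(got$closest$distance, dist)
  }
})

test_that("point overlap and nearest-of-two behave as documented", {
  a <- data.frame(start = 10, end = 20)
  b <- data.frame(start = c(15, 5, 30), end = c(15, 5, 30))
  got <- interval_overlap_and_closest(a, b)
  expect_equal(got$overlaps$b, 1)
  expect_equal(got$closest$distance, 0)
  got2 <- interval_overlap_and_closest(a, b[2:3, , drop = FALSE])
  expect_equal(got2$closest$b, 1)       # point 5, distance -5 (5' side)
  expect_equal(got2$closest$distance, -5)
})

test_that("hybrid/single correlations: exact proportionality and null", {
  ids <- sprintf("M%03d", 1:30)
  hy <- data.frame(target_id = rep(ids, times = 1:30), pos = 100L)
  si <- data.frame(target_id = rep(ids, times = 2 * (1:30)), pos = 150L)
  out <- hybrid_vs_single_stats(hy, si)
  # the +1 in log10(x+1) bends exact 2x proportionality very slightly
  expect_gt(out$correlations$pearson_log10[1], 0.999)
  expect_equal(out$correlations$spearman[1], 1, tolerance = 1e-6)
  # identical counts correlate exactly
  out_id <- hybrid_vs_single_stats(hy, hy)
  expect_equal(out_id$correlations$pearson_log10[1], 1, tolerance = 1e-9)

  set.seed(501)
  ids <- sprintf("N%03d", 1:500)
  hyn <- data.frame(target_id = rep(ids, stats::rpois(500, 3)), pos = 1L)
  sin_ <- data.frame(target_id = rep(ids, stats::rpois(500, 3)), pos = 1L)
  outn <- hybrid_vs_single_stats(hyn, sin_)
  expect_lt(abs(outn$correlations$pearson_log10[1]), 0.15)

  # fewer than 3 mRNAs: correlation undefined, reported as NA
  tiny <- hybrid_vs_single_stats(hy[hy$target_id %in% ids[1:2], ],
                                 si[si$target_id %in% ids[1:2], ])
  expect_true(is.na(tiny$correlations$pearson_log10[1]))
})

test_that("single hits enriched at hybrid starts peak at offset zero", {
  set.seed(502)
  hs <- data.frame(target_id = "M1", pos = c(300L, 700L))
  bg <- data.frame(target_id = "M1", pos = sample(1:1000, 1500, TRUE))
  en <- data.frame(target_id = "M1",
                   pos = rep(hs$pos, each = 1000) +
                     sample(-50:50, 2000, TRUE))
  out <- hybrid_vs_single_stats(hs, rbind(bg, en), window = 200L)
  prof <- out$metaprofile
  # aggregate in 20-nt bins; the central bin must dominate
  bins <- tapply(prof, (abs(as.integer(names(prof)))) %/% 20, sum)
  expect_equal(names(which.max(bins[1:8])), "0")
})
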