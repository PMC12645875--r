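# Intramolecular split, reproducibility clustering, mismap filtering.

# minimal record builder on the tiny annotation's transcript ids
rec <- function(id, tx1, t1, tx2, t2, seq = NULL) {
  l1 <- t1[2] - t1[1] + 1L; l2 <- t2[2] - t2[1] + 1L
  if (is.null(seq)) {
    seq <- paste(sample(c("A", "C", "G", "U"), l1 + l2, TRUE), collapse = "")
  }
  data.frame(read_id = id, read_seq = seq, energy = NA_real_,
             tx1 = tx1, r1_begin = 1L, r1_end = l1,
             t1_begin = t1[1], t1_end = t1[2], score1 = 0.01,
             tx2 = tx2, r2_begin = l1 + 1L, r2_end = l1 + l2,
             t2_begin = t2[1], t2_end = t2[2], score2 = 0.01,
             extra = "", stringsAsFactors = FALSE)
}

test_that("intramolecular split partitions by same-snoRNA identity", {
  ann <- tiny_annotation()
  set.seed(1)
  records <- rbind(
    rec("a", "SNOA", c(10, 40), "SNOA", c(50, 80)),   # internal stem
    rec("b", "SNOA", c(10, 40), "RRN", c(100, 130)),  # intermolecular
    rec("c", "HOSTA", c(10, 40), "HOSTA", c(100, 130)),  # same id, not snoRNA
    rec("d", "SNOA", c(10, 40), "NOSUCH", c(1, 30)))  # unknown id
  sp <- filter_intramolecular(records, ann)
  expect_equal(sp$intra$read_id, "a")
  expect_setequal(sp$inter$read_id, c("b", "c"))
  expect_equal(sp$quarantine$read_id, "d")
  expect_equal(nrow(sp$inter) + nrow(sp$intra) + nrow(sp$quarantine),
               nrow(records))
  # idempotent on its own output
  sp2 <- filter_intramolecular(sp$inter, ann)
  expect_equal(nrow(sp2$intra), 0)
  expect_equal(sp2$inter$read_id, sp$inter$read_id)
})

test_that("identical records form one reproducible cluster of support 2", {
  set.seed(2)
  r <- rec("x1", "SNOA", c(10, 40), "RRN", c(100, 130))
  r2 <- r; r2$read_id <- "x2"
  cl <- cluster_reproducible(rbind(r, r2))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$support, 2)
  expect_true(cl$reproducible)
  expect_equal(cl$members, "x1,x2")
})

test_that("records at disjoint target intervals stay separate singletons", {
  set.seed(3)
  cl <- cluster_reproducible(rbind(
    rec("x1", "SNOA", c(10, 40), "RRN", c(100, 130)),
    rec("x2", "SNOA", c(10, 40), "RRN", c(200, 230))))
  expect_equal(nrow(cl), 2)
  expect_false(any(cl$reproducible))
})

test_that("linking requires overlap on both fragments; read order is ignored", {
  set.seed(4)
  a <- rec("a", "SNOA", c(10, 40), "RRN", c(100, 130))
  # same snoRNA span but swapped fragment order on the read
  b <- rec("b", "RRN", c(105, 135), "SNOA", c(15, 45))
  # overlaps a on the snoRNA side only
  c_ <- rec("c", "SNOA", c(10, 40), "RRN", c(300, 330))
  cl <- cluster_reproducible(rbind(a, b, c_))
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$support, c(2L, 1L))
  expect_equal(cl$members[cl$support == 2], "a,b")
})

test_that("planted duplicate design recovers exactly the planted clusters", {
  set.seed(5)
  n <- 6; k <- 3; m <- 4
  planted <- lapply(seq_len(n), function(i) {
    base <- rec(sprintf("p%d_1", i), "SNOA", c(10 + 60 * i, 40 + 60 * i),
                "RRN", c(100 * i, 100 * i + 30))
    do.call(rbind, lapply(seq_len(k), function(j) {
      x <- base; x$read_id <- sprintf("p%d_%d", i, j); x
    }))
  })
  singles <- lapply(seq_len(m), function(i) {
    rec(sprintf("s%d", i), "SNOA", c(2000 + 60 * i, 2030 + 60 * i),
        "RRN", c(3000 + 100 * i, 3030 + 100 * i))
  })
  records <- do.call(rbind, c(planted, singles))
  cl <- cluster_reproducible(records)
  expect_equal(sum(cl$reproducible), n)
  expect_equal(sum(!cl$reproducible), m)
  expect_true(all(cl$support[cl$reproducible] == k))
})

test_that("clustering is invariant under input permutation", {
  set.seed(6)
  records <- rbind(
    rec("a1", "SNOA", c(10, 40), "RRN", c(100, 130)),
    rec("a2", "SNOA", c(20, 50), "RRN", c(110, 140)),
    rec("b1", "SNOA", c(200, 230), "RRN", c(100, 130)),
    rec("c1", "SNOA", c(10, 40), "HOSTA", c(500, 530)),
    rec("c2", "SNOA", c(12, 42), "HOSTA", c(505, 535)))
  ref <- cluster_reproducible(records)
  key <- ref[order(ref$members), c("members", "support", "t1_begin",
                                   "t2_end")]
  rownames(key) <- NULL
  for (s in 1:20) {
    set.seed(s)
    perm <- cluster_reproducible(records[sample(nrow(records)), ])
    pk <- perm[order(perm$members), c("members", "support", "t1_begin",
                                      "t2_end")]
    rownames(pk) <- NULL
    expect_identical(pk, key)
  }
})

test_that("mismap filter removes verbatim decoy copies, keeps the rest", {
  ann <- tiny_annotation()
  decoys <- list(U3_SYN = paste(rep(c("A", "C", "G", "U"), 50),
                                collapse = ""))
  set.seed(7)
  decoys$U3_SYN <- paste(sample(c("A", "C", "G", "U"), 200, TRUE),
                         collapse = "")
  u3_frag <- substring(decoys$U3_SYN, 50, 84)
  sno_part <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
  # snoRNA-mRNA record whose mRNA fragment is a verbatim U3 substring
  bad <- rec("bad", "SNOA", c(10, 39), "HOSTA", c(300, 334),
             seq = paste0(sno_part, u3_frag))
  good <- rec("good", "SNOA", c(10, 39), "HOSTA", c(300, 334))
  # snoRNA-rRNA record: out of the filter's scope
  rrna <- rec("rrna", "SNOA", c(10, 39), "RRN", c(100, 134),
              seq = paste0(sno_part, u3_frag))
  out <- filter_mismap(rbind(bad, good, rrna), unlist(decoys), ann)
  expect_equal(out$removed$read_id, "bad")
  expect_setequal(out$kept$read_id, c("good", "rrna"))
  expect_false(out$report$applied[out$report$read_id == "rrna"])
  expect_equal(nrow(out$kept) + nrow(out$removed), 3)
  # idempotent: re-filtering the kept set removes nothing
  out2 <- filter_mismap(out$kept, unlist(decoys), ann)
  expect_equal(nrow(out2$removed), 0)
  # an empty decoy set must not silently no-op
  expect_error(filter_mismap(rbind(bad), character(0), ann), "decoy")
})

test_that("pair-type summary counts and fractions are conserved", {
  ann <- tiny_annotation()
  set.seed(8)
  records <- rbind(
    rec("a1", "SNOA", c(10, 40), "RRN", c(100, 130)),
    rec("a2", "SNOA", c(10, 40), "RRN", c(100, 130)),
    rec("b1", "SNOA", c(10, 40), "HOSTA", c(500, 530)),
    rec("b2", "SNOA", c(10, 40), "HOSTA", c(500, 530)))
  cl <- cluster_reproducible(records)
  tab <- summarize_pair_types(cl, ann)
  expect_equal(sum(tab$count), nrow(cl))
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
  expect_true(all(tab$biotype1 == "snoRNA"))
  # empty input -> empty table
  empty <- summarize_pair_types(cl[0, ], ann)
  expect_equal(nrow(empty), 0)
})
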