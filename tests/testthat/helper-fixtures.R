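# Shared fixtures, built in code at test time.

# --- tiny hand-built annotation ----------------------------------------
# chrSYN layout (1-based closed genomic coordinates):
#   HOSTA (+): exons 1001-1100, 1301-1400, 1601-1700; CDS 1051-1650
#              -> introns local 101-300 and 401-600
#   SNOA  (+): single exon 1121-1200 (80 nt) inside HOSTA intron 1
#   RRN   (+): single exon 3001-3500 (500 nt), rRNA
#   MREV  (-): exons 5001-5100, 5201-5300, 5401-5500 (3-exon minus strand)
tiny_annotation_files <- function(dir = withr::local_tempdir(
                                    .local_envir = parent.frame())) {
  gtf <- file.path(dir, "tiny.gtf")
  fa <- file.path(dir, "tiny.fa")
  sites <- file.path(dir, "tiny_sites.tsv")
  at <- function(id, bt) sprintf(
    'gene_id "%s"; transcript_id "%s"; biotype "%s";', id, id, bt)
  lines <- c(
    paste("chrSYN", "t", "exon", 1001, 1100, ".", "+", ".",
          at("HOSTA", "mRNA"), sep = "\t"),
    paste("chrSYN", "t", "exon", 1301, 1400, ".", "+", ".",
          at("HOSTA", "mRNA"), sep = "\t"),
    paste("chrSYN", "t", "exon", 1601, 1700, ".", "+", ".",
          at("HOSTA", "mRNA"), sep = "\t"),
    paste("chrSYN", "t", "CDS", 1051, 1100, ".", "+", "0",
          at("HOSTA", "mRNA"), sep = "\t"),
    paste("chrSYN", "t", "CDS", 1301, 1400, ".", "+", "0",
          at("HOSTA", "mRNA"), sep = "\t"),
    paste("chrSYN", "t", "CDS", 1601, 1650, ".", "+", "0",
          at("HOSTA", "mRNA"), sep = "\t"),
    paste("chrSYN", "t", "exon", 1121, 1200, ".", "+", ".",
          at("SNOA", "snoRNA"), sep = "\t"),
    paste("chrSYN", "t", "exon", 3001, 3500, ".", "+", ".",
          at("RRN", "rRNA"), sep = "\t"),
    paste("chrSYN", "t", "exon", 5001, 5100, ".", "-", ".",
          at("MREV", "mRNA"), sep = "\t"),
    paste("chrSYN", "t", "exon", 5201, 5300, ".", "-", ".",
          at("MREV", "mRNA"), sep = "\t"),
    paste("chrSYN", "t", "exon", 5401, 5500, ".", "-", ".",
          at("MREV", "mRNA"), sep = "\t"))
  writeLines(lines, gtf)
  set.seed(99)
  rs <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  hosta <- rs(700)
  snoa <- substr(hosta, 121, 200)   # embedded: FASTA consistent with host
  writeLines(c(">HOSTA", hosta, ">SNOA", snoa, ">RRN", rs(500),
               ">MREV", rs(500)), fa)
  writeLines(c("target_id\tposition\tguide_family\tbox\tsource",
               "RRN\t100\tSNOA\tD\ttest",
               "RRN\t250\tFAMX\tD\ttest"), sites)
  list(gtf = gtf, fasta = fa, sites = sites)
}

tiny_annotation <- function() {
  f <- tiny_annotation_files()
  read_annotation(f$gtf, f$fasta, f$sites)
}

# --- shared synthetic bundle (generated once per test run) -------------
.synth_cache <- new.env(parent = emptyenv())

shared_synth <- function() {
  if (is.null(.synth_cache$bundle)) {
    dir <- file.path(tempdir(), "snoclash_shared_synth")
    cfg <- synthetic_config(seed = 11, n_interactions = 14)
    ref <- generate_reference(cfg, dir = dir)
    chim <- generate_chimeras(cfg, ref, dir = dir)
    pc <- pipeline_config(chimeras = chim$files$hyb, gtf = ref$files$gtf,
                          fasta = ref$files$fasta, sites = ref$files$sites,
                          boxes = ref$files$boxes,
                          out_dir = file.path(dir, "run"))
    res <- run_pipeline(pc, quiet = TRUE)
    .synth_cache$bundle <- list(cfg = cfg, ref = ref, chim = chim,
                                config = pc, result = res)
  }
  .synth_cache$bundle
}

# random chimera record table for round-trip tests
random_chimeras <- function(n, seed) {
  set.seed(seed)
  rs <- function(k) paste(sample(c("A", "C", "G", "U"), k, TRUE),
                          collapse = "")
  rows <- lapply(seq_len(n), function(i) {
    l1 <- sample(20:35, 1); l2 <- sample(20:35, 1)
    data.frame(read_id = sprintf("r%04d", i), read_seq = rs(l1 + l2),
               energy = if (i %% 3 == 0) NA_real_ else
                 -round(stats::runif(1, 5, 30), 2),
               tx1 = sample(c("SNO1", "SNO2", "SNO3"), 1),
               r1_begin = 1L, r1_end = l1,
               t1_begin = sample(1:50, 1), t1_end = 0L, score1 = 0.01,
               tx2 = sample(c("T1", "T2"), 1),
               r2_begin = l1 + 1L, r2_end = l1 + l2,
               t2_begin = sample(1:400, 1), t2_end = 0L, score2 = 0.02,
               extra = if (i %% 5 == 0) "x\ty" else "",
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$t1_end <- df$t1_begin + (df$r1_end - df$r1_begin)
  df$t2_end <- df$t2_begin + (df$r2_end - df$r2_begin)
  df
}

# a guide_geometry object built directly from pairing vectors
make_geom <- function(exact16, paired16 = exact16, box_exact4 = rep(FALSE, 4),
                      n_total = sum(paired16), box = "D") {
  structure(list(
    box = box,
    offsets = data.frame(k = 1:16, sno_pos = 100 - (1:16),
                         paired = paired16, exact = exact16,
                         target_pos = ifelse(paired16, 200 + (1:16),
                                             NA_integer_)),
    box_exact = box_exact4, n_pairs_total = n_total,
    predicted_target_pos = if (paired16[5]) 205L else NA_integer_),
    class = "guide_geometry")
}

# a duplex object with k perfect G-C pairs, target side = fragment 2
gc_duplex <- function(k, len = 25L) {
  structure(list(pairs = cbind(i = seq_len(k), j = rev(seq_len(k))),
                 n_pairs = k, dG = -30,
                 structure = paste0(strrep("(", k), strrep(".", len - k),
                                    "&", strrep(".", len - k),
                                    strrep(")", k)),
                 seq1 = strrep("G", len), seq2 = strrep("C", len),
                 params = duplex_params()),
            class = "duplex")
}
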