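# Seed-deterministic synthetic data: ground-truth-labelled references,
# chimeras, and single reads emulating a box C/D snoRNA CLASH experiment.
#
# Every snoRNA follows a fixed architecture (local 1-based coordinates):
#   1-4 lead | 5-11 box C (AUGAUGA) | 12-37 accessory | 38-43 spacer |
#   44-55 guide | 56-59 box D (CUGA) | 60-62 tail        (length 62 nt)
# Each snoRNA is embedded mid-intron in its own host gene (exon 200 /
# intron 600 / exon 200, CDS on both exons) at host-local 401-462, so the
# reference database extends it by `flank` nt into intronic sequence.
# Interaction classes are engineered on a synthetic pre-rRNA:
# methylation guides pair the guide region (the +5 rule places the site
# opposite offset 5); ancillary/blocking/structural interactions pair the
# accessory region, which lies further than 16 nt upstream of box D, so
# the guide-geometry offsets stay unpaired. Truth labels are verified at
# generation time with the naive rule checker (rulecheck.R), never with
# the classifier under test.

.SNO_ARCH <- list(lead = c(1L, 4L), boxC = c(5L, 11L), accessory = c(12L, 37L),
                  spacer = c(38L, 43L), guide = c(44L, 55L),
                  boxD = c(56L, 59L), tail = c(60L, 62L), len = 62L)

.CLASSES <- c("methylation_strict", "methylation_weak", "ancillary",
              "blocking", "structural", "intramolecular_stem", "mismap_decoy")

.rand_seq <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                               collapse = "")

#' Configuration of the synthetic-data generator
#'
#' The defaults emulate the experimental conditions the pipeline targets:
#' snoRNA fragments of chimeras average 35-40 nt, interactions are
#' supported by several independent reads, and every decision-tree class
#' is represented.
#'
#' @param seed integer; fully determines all outputs.
#' @param n_interactions total interactions to plant.
#' @param class_mix named proportions over the seven classes
#'   (methylation_strict, methylation_weak, ancillary, blocking,
#'   structural, intramolecular_stem, mismap_decoy); must sum to 1.
#' @param duplicate_rate fraction of interactions receiving >= 2
#'   supporting reads (the rest are singletons).
#' @param support_range inclusive range of supporting reads per
#'   duplicated interaction.
#' @param jitter_max maximum per-copy jitter (nt) on fragment pads.
#' @param noise_rate per-base substitution rate on read sequences
#'   (criterion-critical positions are never mutated, so truth labels
#'   stay valid).
#' @param frag_pad_guide,frag_pad_target pad ranges (nt) around the
#'   planted regions when cutting fragments.
#' @param n_mrnas number of mRNA target genes (mismap-claimed targets and
#'   single-read hosts).
#' @param flank reference-database snoRNA extension, nt.
#' @param n_single_reads,single_enrichment,single_window single-read
#'   generator: total hits, fold-enrichment around hybrid starts, and
#'   enrichment half-window (nt).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_interactions = 70L,
                             class_mix = NULL, duplicate_rate = 1.0,
                             support_range = c(2L, 4L), jitter_max = 2L,
                             noise_rate = 0,
                             frag_pad_guide = c(2L, 6L),
                             frag_pad_target = c(4L, 8L),
                             n_mrnas = 4L, flank = 20L,
                             n_single_reads = 2000L, single_enrichment = 5,
                             single_window = 50L) {
  if (is.null(class_mix)) {
    class_mix <- stats::setNames(rep(1 / length(.CLASSES), length(.CLASSES)),
                                 .CLASSES)
  }
  stopifnot(abs(sum(class_mix) - 1) < 1e-9,
            all(names(class_mix) %in% .CLASSES),
            duplicate_rate >= 0, duplicate_rate <= 1,
            support_range[1] >= 2L, noise_rate >= 0, noise_rate < 1)
  structure(list(seed = as.integer(seed),
                 n_interactions = as.integer(n_interactions),
                 class_mix = class_mix,
                 duplicate_rate = duplicate_rate,
                 support_range = as.integer(support_range),
                 jitter_max = as.integer(jitter_max),
                 noise_rate = noise_rate,
                 frag_pad_guide = as.integer(frag_pad_guide),
                 frag_pad_target = as.integer(frag_pad_target),
                 n_mrnas = as.integer(n_mrnas), flank = as.integer(flank),
                 n_single_reads = as.integer(n_single_reads),
                 single_enrichment = single_enrichment,
                 single_window = as.integer(single_window)),
            class = "synthetic_config")
}

# class counts from mix (largest-remainder rounding, deterministic)
.class_counts <- function(cfg) {
  raw <- cfg$class_mix * cfg$n_interactions
  base <- floor(raw)
  rem <- cfg$n_interactions - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(cfg$class_mix))
}

# --- independent per-class verification helpers (no classifier code) ----

# geometry vectors for the naive checker, computed directly from a duplex
.naive_geom <- function(duplex, sno_frag_entry, boxD_entry_start,
                        target_frag) {
  ch1 <- .chars(duplex$seq1); ch2 <- .chars(duplex$seq2)
  p <- duplex$pairs
  state <- function(sno_entry_pos) {
    if (sno_entry_pos < sno_frag_entry[1] || sno_entry_pos > sno_frag_entry[2])
      return(c(FALSE, FALSE, NA))
    loc <- sno_entry_pos - sno_frag_entry[1] + 1L
    hit <- which(p[, 1] == loc)
    if (!length(hit)) return(c(FALSE, FALSE, NA))
    a <- ch1[p[hit, 1]]; b <- ch2[p[hit, 2]]
    wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")
    c(TRUE, wc, target_frag[1] + p[hit, 2] - 1L)
  }
  up <- t(vapply(boxD_entry_start - (1:16), state, c(0, 0, 0)))
  bx <- t(vapply(boxD_entry_start + (0:3), state, c(0, 0, 0)))
  list(paired16 = as.logical(up[, 1]), exact16 = as.logical(up[, 2]),
       target16 = up[, 3], box_exact4 = as.logical(bx[, 2]),
       n_total = nrow(p))
}

# WC-pair count within +/- flank of a site, computed independently
.naive_wc_near <- function(duplex, target_frag, site, flank) {
  ch1 <- .chars(duplex$seq1); ch2 <- .chars(duplex$seq2)
  p <- duplex$pairs
  if (!nrow(p)) return(0L)
  a <- ch1[p[, 1]]; b <- ch2[p[, 2]]
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  tpos <- target_frag[1] + p[, 2] - 1L
  sum(wc & tpos >= site - flank & tpos <= site + flank)
}

# --- reference + interaction plan ---------------------------------------

#' Generate the synthetic reference and interaction plan
#'
#' Builds snoRNA/host/mRNA/pre-rRNA/U3-decoy sequences with planted
#' ground truth, verifies every planted interaction against the naive
#' rule checker and the energy threshold (resampling random filler on
#' failure), and optionally writes the reference files (GTF, FASTA of
#' unspliced per-transcript sequences, known-site TSV, curated box TSV).
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory for
#'   `reference.gtf`, `reference.fa`, `sites.tsv`, `boxes.tsv`.
#' @return list of class `synthetic_reference`: `annotation`
#'   (`annotation_set`), `db` (`reference_db`), `boxes` (curated list),
#'   `plan` (per-copy fragment plan with truth labels), `files`.
#' @export
generate_reference <- function(cfg, dir = NULL) {
  set.seed(cfg$seed)
  counts <- .class_counts(cfg)
  classes <- rep(names(counts), counts)
  n <- length(classes)
  A <- .SNO_ARCH
  fl <- cfg$flank
  boxD_entry <- A$boxD[1] + fl          # box D start on the extended entry

  n_M <- sum(classes == "mismap_decoy")
  u3_len <- 60L + 40L * max(1L, n_M)
  u3 <- .chars(.rand_seq(u3_len))

  # pre-rRNA slot layout
  slot_w <- c(methylation_strict = 70L, methylation_weak = 70L,
              ancillary = 150L, blocking = 80L, structural = 70L,
              intramolecular_stem = 0L, mismap_decoy = 0L)
  cursor <- 100L
  slot_start <- integer(n)
  for (i in seq_len(n)) {
    w <- slot_w[[classes[i]]]
    slot_start[i] <- if (w > 0) cursor else NA_integer_
    if (w > 0) cursor <- cursor + w + 20L
  }
  rrna_len <- cursor + 200L
  rrna <- .chars(.rand_seq(rrna_len))

  transcripts <- list(); sequences <- character(0)
  plc_rows <- list(); site_rows <- list(); boxes <- list(); plan <- list()
  gcursor <- 1L
  mrna_ids <- sprintf("MRNA_T%d", seq_len(cfg$n_mrnas))
  u3_id <- "U3_SYN"; rrna_id <- "RNA45S_SYN"
  decoy_i <- 0L

  add_gene <- function(id, gene_id, biotype, local_len, strand,
                       exons_local, cds_local = NULL, seq = NULL,
                       parent = NULL) {
    # `parent`: list(host_id, sno_local_span) for embedded snoRNA genes
    if (is.null(parent)) {
      gs <- gcursor
      gcursor <<- gcursor + local_len + 500L
    } else {
      host <- transcripts[[parent$host_id]]
      sl <- parent$span
      gs <- if (host$strand == "+") host$gene_start + sl[1] - 1L
            else host$gene_start + (host$span_len - sl[2])
    }
    ge <- gs + local_len - 1L
    to_g <- function(iv) {
      if (strand == "+") c(gs + iv[1] - 1L, gs + iv[2] - 1L)
      else c(gs + local_len - iv[2], gs + local_len - iv[1])
    }
    ex_g <- t(apply(exons_local, 1, to_g))
    cds_g <- if (!is.null(cds_local)) range(c(to_g(cds_local))) else NULL
    transcripts[[id]] <<- .make_transcript_model(id, gene_id, "chrSYN",
                                                 strand, ex_g, cds_g, biotype)
    sequences[[id]] <<- seq
    invisible(NULL)
  }

  one_exon <- function(L) matrix(c(1L, L), 1, dimnames = list(NULL,
                                                              c("start", "end")))
  host_exons <- rbind(c(1L, 200L), c(801L, 1000L))
  colnames(host_exons) <- c("start", "end")

  pads <- function(rng, jmax) {
    base <- c(sample(rng[1]:rng[2], 1), sample(rng[1]:rng[2], 1))
    function() pmax(0L, base + sample(0:jmax, 2, TRUE))
  }

  params <- duplex_params()
  for (i in seq_len(n)) {
    cl <- classes[i]
    sno_id <- sprintf("SNO%04d", i)
    host_id <- sprintf("HOST%04d", i)
    strand <- if (i %% 3 == 0) "-" else "+"
    site_pos <- NA_integer_

    ok <- FALSE
    for (attempt in 1:40) {
      lead <- .rand_seq(4); accessory <- .rand_seq(26); spacer <- .rand_seq(6)
      guide <- .chars(.rand_seq(12)); tail <- .rand_seq(3)
      if (cl == "methylation_weak") {
        # offset 5 -> guide position 8, offset 10 -> guide position 3
        guide[8] <- "G"; guide[3] <- "G"
      }
      sno_seq <- paste0(lead, "AUGAUGA", accessory, spacer,
                        paste(guide, collapse = ""), "CUGA", tail)
      slot <- NULL; u3_patch <- NULL
      if (cl %in% c("methylation_strict", "methylation_weak")) {
        w <- slot_w[[cl]]
        slot <- .chars(.rand_seq(w))
        t_in_slot <- 40L                     # site, slot-local
        site_pos <- slot_start[i] + t_in_slot - 1L
        anti <- .chars(revcomp_rna(paste(guide, collapse = "")))
        slot[(t_in_slot - 4):(t_in_slot + 7)] <- anti
        slot[(t_in_slot - 8):(t_in_slot - 5)] <- c("A", "A", "C", "C")
        if (cl == "methylation_weak") {
          slot[t_in_slot] <- "U"             # partner of offset 5: G-U
          slot[t_in_slot + 5] <- "U"         # partner of offset 10: G-U
        }
      } else if (cl == "ancillary") {
        w <- slot_w[[cl]]
        slot <- .chars(.rand_seq(w))
        anti <- .chars(revcomp_rna(substr(paste0(accessory), 1, 14)))
        slot[10:23] <- anti
        d <- sample(25:95, 1)
        site_pos <- slot_start[i] + 23L + d - 1L
      } else if (cl == "blocking") {
        w <- slot_w[[cl]]
        slot <- .chars(.rand_seq(w))
        anti <- .chars(revcomp_rna(substr(accessory, 1, 24)))
        slot[28:51] <- anti
        site_pos <- slot_start[i] + 40L - 1L  # slot-local 40 = region centre
      } else if (cl == "structural") {
        w <- slot_w[[cl]]
        slot <- .chars(.rand_seq(w))
        anti <- .chars(revcomp_rna(substr(accessory, 1, 14)))
        slot[10:23] <- anti
      } else if (cl == "mismap_decoy") {
        u <- 30L + 40L * decoy_i
        u3_patch <- list(pos = u,
                         anti = .chars(revcomp_rna(substr(accessory, 1, 14))))
      }

      # fragment plan for each supporting copy
      support <- if (stats::runif(1) < cfg$duplicate_rate) {
        sample(cfg$support_range[1]:cfg$support_range[2], 1)
      } else 1L
      padf <- if (cl %in% c("methylation_strict", "methylation_weak")) {
        pads(cfg$frag_pad_guide, cfg$jitter_max)
      } else pads(c(2L, 4L), cfg$jitter_max)
      tpadf <- pads(cfg$frag_pad_target, cfg$jitter_max)

      copies <- lapply(seq_len(support), function(cp) {
        p1 <- padf(); p2 <- tpadf()
        if (cl %in% c("methylation_strict", "methylation_weak")) {
          sf <- c(A$boxD[1] - 16L - p1[1], A$boxD[2] + 3L) + fl
          tf <- c(40L - 8L - p2[1], 40L + 7L + p2[2])
        } else if (cl %in% c("ancillary", "structural")) {
          sf <- c(A$accessory[1] - p1[1], A$accessory[1] + 13L + min(p1[2], 4L)) + fl
          tf <- c(10L - p2[1], 23L + min(p2[2], 6L))
        } else if (cl == "blocking") {
          sf <- c(A$accessory[1] - p1[1], A$accessory[1] + 23L + min(p1[2], 4L)) + fl
          tf <- c(28L - p2[1], 51L + p2[2])
        } else if (cl == "mismap_decoy") {
          sf <- c(A$accessory[1] - p1[1], A$accessory[1] + 13L + min(p1[2], 4L)) + fl
          tf <- c(-10L, 23L)                 # relative to the U3 plant
        } else {                             # intramolecular stem
          sf <- c(1L, 30L) + fl
          tf <- c(35L, 62L) + fl
        }
        list(sno_frag = sf, target_frag = tf)
      })

      # --- verification against the naive rules -------------------------
      # entry = sno extended by flank into the (randomised) intron context
      intron_left <- .rand_seq(fl); intron_right <- .rand_seq(fl)
      entry_seq <- paste0(intron_left, sno_seq, intron_right)

      verify <- TRUE
      if (cl == "intramolecular_stem") {
        verify <- TRUE
      } else if (cl == "mismap_decoy") {
        u <- u3_patch$pos
        u3_try <- u3
        u3_try[u:(u + 13L)] <- u3_patch$anti
        for (cpy in copies) {
          f2 <- paste(u3_try[(u + cpy$target_frag[1]):(u + cpy$target_frag[2])],
                      collapse = "")
          f1 <- .subseq1(entry_seq, cpy$sno_frag[1], cpy$sno_frag[2])
          d <- predict_duplex(f1, f2, params)
          if (!energy_filter(d)) { verify <- FALSE; break }
        }
      } else {
        slot_seq <- paste(slot, collapse = "")
        for (cpy in copies) {
          f1 <- .subseq1(entry_seq, cpy$sno_frag[1], cpy$sno_frag[2])
          tf <- cpy$target_frag
          f2 <- .subseq1(slot_seq, tf[1], tf[2])
          tf_abs1 <- tf + slot_start[i] - 1L
          d <- predict_duplex(f1, f2, params)
          if (!energy_filter(d)) { verify <- FALSE; break }
          g <- .naive_geom(d, cpy$sno_frag, boxD_entry, tf_abs1)
          call <- naive_guide_call(g$exact16, g$paired16, g$box_exact4,
                                   g$n_total)
          want <- switch(cl, methylation_strict = "strict",
                         methylation_weak = "weak", "none")
          if (call != want) { verify <- FALSE; break }
          if (cl == "methylation_strict" &&
              !identical(g$target16[5], as.numeric(site_pos))) {
            verify <- FALSE; break
          }
          if (cl == "blocking" &&
              .naive_wc_near(d, tf_abs1, site_pos, 17L) < 22L) {
            verify <- FALSE; break
          }
          if (cl %in% c("ancillary", "structural") &&
              .naive_wc_near(d, tf_abs1,
                             if (is.na(site_pos)) -1e6 else site_pos,
                             17L) >= 22L) {
            verify <- FALSE; break
          }
        }
      }
      if (!verify) next

      # --- commit this interaction --------------------------------------
      if (!is.null(slot)) rrna[slot_start[i]:(slot_start[i] +
                                                length(slot) - 1L)] <- slot
      if (!is.null(u3_patch)) {
        u3[u3_patch$pos:(u3_patch$pos + 13L)] <- u3_patch$anti
        decoy_i <- decoy_i + 1L
      }
      # host local: exon1 200 + intron start (random), then the snoRNA with
      # the flanking context used for the extended entry, intron rest, exon2
      host_seq <- paste0(.rand_seq(400 - fl), intron_left, sno_seq,
                         intron_right, .rand_seq(338 - fl), .rand_seq(200))
      add_gene(host_id, host_id, "mRNA", 1000L, strand, host_exons,
               cds_local = c(51L, 900L), seq = host_seq)
      add_gene(sno_id, sno_id, "snoRNA", A$len, strand, one_exon(A$len),
               seq = sno_seq, parent = list(host_id = host_id,
                                            span = c(401L, 462L)))
      plc_rows[[length(plc_rows) + 1L]] <- data.frame(
        snorna_id = sno_id, host_tx = host_id, host_intron = 1L,
        sno_local_start = 401L, sno_local_end = 462L, stringsAsFactors = FALSE)
      boxes[[sno_id]] <- box_annotation(sno_id, boxC_start = A$boxC[1] + fl,
                                        boxD_start = boxD_entry)
      if (!is.na(site_pos)) {
        fam <- if (cl == "blocking") sprintf("EXTFAM%04d", i) else sno_id
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          target_id = rrna_id, position = site_pos, guide_family = fam,
          box = if (cl %in% c("methylation_strict", "methylation_weak"))
            "D" else "unknown",
          source = "synthetic", stringsAsFactors = FALSE)
      }
      target_id <- switch(cl,
                          intramolecular_stem = sno_id,
                          mismap_decoy = mrna_ids[(i %% cfg$n_mrnas) + 1L],
                          rrna_id)
      plan[[length(plan) + 1L]] <- data.frame(
        interaction_id = sprintf("I%04d", i), class = cl, sno_id = sno_id,
        target_id = target_id, site_pos = site_pos,
        support = length(copies),
        copy = seq_along(copies),
        sno_start = vapply(copies, function(x) x$sno_frag[1], integer(1)),
        sno_end = vapply(copies, function(x) x$sno_frag[2], integer(1)),
        t_start = vapply(copies, function(x) {
          if (cl %in% c("intramolecular_stem")) x$target_frag[1]
          else if (cl == "mismap_decoy") x$target_frag[1]
          else x$target_frag[1] + slot_start[i] - 1L
        }, integer(1)),
        t_end = vapply(copies, function(x) {
          if (cl %in% c("intramolecular_stem")) x$target_frag[2]
          else if (cl == "mismap_decoy") x$target_frag[2]
          else x$target_frag[2] + slot_start[i] - 1L
        }, integer(1)),
        u3_pos = if (cl == "mismap_decoy") u3_patch$pos else NA_integer_,
        stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not realise a valid '", cl,
                  "' interaction after 40 attempts")
  }

  # shared targets
  add_gene(rrna_id, rrna_id, "rRNA", rrna_len, "+", one_exon(rrna_len),
           seq = paste(rrna, collapse = ""))
  add_gene(u3_id, u3_id, "snoRNA", u3_len, "+", one_exon(u3_len),
           seq = paste(u3, collapse = ""))
  for (mid in mrna_ids) {
    add_gene(mid, mid, "mRNA", 1000L, "+", host_exons,
             cds_local = c(51L, 900L), seq = .rand_seq(1000))
  }

  sno_placements <- do.call(rbind, plc_rows)
  known_sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    read_known_sites(NULL)
  annotation <- structure(list(transcripts = transcripts,
                               sno_placements = sno_placements,
                               known_sites = known_sites,
                               sequences = unlist(sequences)),
                          class = "annotation_set")
  db <- build_reference_db(annotation, flank = fl)
  plan <- do.call(rbind, plan)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(gtf = file.path(dir, "reference.gtf"),
                  fasta = file.path(dir, "reference.fa"),
                  sites = file.path(dir, "sites.tsv"),
                  boxes = file.path(dir, "boxes.tsv"))
    .write_gtf(annotation, files$gtf)
    write_reference_fasta(annotation$sequences, files$fasta)
    utils::write.table(known_sites, files$sites, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_box_annotation(boxes, files$boxes)
  }
  structure(list(annotation = annotation, db = db, boxes = boxes,
                 plan = plan, files = files, config = cfg),
            class = "synthetic_reference")
}

# minimal GTF writer (exon + CDS lines, attributes gene_id/transcript_id/
# biotype); read back with rtracklayer in read_annotation()
.write_gtf <- function(annotation, path) {
  lines <- character(0)
  for (tx in annotation$transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";',
                     tx$gene_id, tx$transcript_id, tx$biotype)
    for (k in seq_len(nrow(tx$exons_g))) {
      lines <- c(lines, paste("chrSYN", "synthetic", "exon",
                              tx$exons_g[k, 1], tx$exons_g[k, 2], ".",
                              tx$strand, ".", attrs, sep = "\t"))
    }
    if (!is.null(tx$cds_g)) {
      for (k in seq_len(nrow(tx$exons_g))) {
        cs <- max(tx$exons_g[k, 1], tx$cds_g[1])
        ce <- min(tx$exons_g[k, 2], tx$cds_g[2])
        if (cs <= ce) {
          lines <- c(lines, paste("chrSYN", "synthetic", "CDS", cs, ce, ".",
                                  tx$strand, "0", attrs, sep = "\t"))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate chimeric reads (hyb file) with truth labels
#'
#' Materialises the interaction plan of a [generate_reference()] result
#' into hyb-format chimera records plus a truth table. Substitution noise
#' (if configured) is applied to read sequences only, never at
#' criterion-critical positions.
#'
#' @param cfg a [synthetic_config()].
#' @param ref a `synthetic_reference`.
#' @param dir optional output directory for `chimeras.hyb` and
#'   `truth.tsv`.
#' @return list `chimeras` (hyb data.frame), `truth` (data.frame),
#'   `files`.
#' @export
generate_chimeras <- function(cfg, ref, dir = NULL) {
  set.seed(cfg$seed + 1L)
  plan <- ref$plan
  db <- ref$db
  u3 <- db$sequences[["U3_SYN"]]
  recs <- list(); truth <- list()
  for (r in seq_len(nrow(plan))) {
    cl <- plan$class[r]
    sno_id <- plan$sno_id[r]; target_id <- plan$target_id[r]
    s1 <- plan$sno_start[r]; e1 <- plan$sno_end[r]
    s2 <- plan$t_start[r]; e2 <- plan$t_end[r]
    f1 <- .subseq1(db$sequences[[sno_id]], s1, e1)
    f2 <- if (cl == "mismap_decoy") {
      u <- plan$u3_pos[r]
      .subseq1(u3, u + s2, u + e2)
    } else if (cl == "intramolecular_stem") {
      .subseq1(db$sequences[[sno_id]], s2, e2)
    } else {
      .subseq1(db$sequences[[target_id]], s2, e2)
    }
    if (cl == "mismap_decoy") {
      # claimed coordinates on the mRNA intron; sequence is the U3 copy
      s2 <- 301L; e2 <- 301L + nchar(f2) - 1L
    }
    read_seq <- paste0(f1, f2)
    L1 <- nchar(f1); L2 <- nchar(f2)
    critical <- switch(cl,
      methylation_strict = ,
      methylation_weak = c(
        # guide + box D on the snoRNA side, planted region on the target
        which(seq(s1, e1) >= .SNO_ARCH$guide[1] + cfg$flank &
                seq(s1, e1) <= .SNO_ARCH$boxD[2] + cfg$flank),
        L1 + which(seq(s2, e2) >= plan$site_pos[r] - 8L &
                     seq(s2, e2) <= plan$site_pos[r] + 7L)),
      ancillary = ,
      structural = ,
      blocking = c(seq_len(L1), L1 + seq_len(L2)),
      mismap_decoy = c(seq_len(L1), L1 + seq_len(L2)),
      integer(0))
    if (cfg$noise_rate > 0) {
      mut <- which(stats::runif(L1 + L2) < cfg$noise_rate)
      mut <- setdiff(mut, critical)
      if (length(mut)) {
        ch <- .chars(read_seq)
        ch[mut] <- vapply(ch[mut], function(b)
          sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1))
        read_seq <- paste(ch, collapse = "")
      }
    }
    read_id <- sprintf("%s_r%d", plan$interaction_id[r], plan$copy[r])
    recs[[r]] <- data.frame(
      read_id = read_id, read_seq = read_seq, energy = NA_real_,
      tx1 = sno_id, r1_begin = 1L, r1_end = L1,
      t1_begin = s1, t1_end = e1, score1 = 0.001,
      tx2 = if (cl == "intramolecular_stem") sno_id else target_id,
      r2_begin = L1 + 1L, r2_end = L1 + L2,
      t2_begin = s2, t2_end = e2, score2 = 0.001,
      extra = "", stringsAsFactors = FALSE)
    truth[[r]] <- data.frame(
      read_id = read_id, interaction_id = plan$interaction_id[r],
      class = cl, sno_id = sno_id, target_id = plan$target_id[r],
      box = if (cl %in% c("methylation_strict", "methylation_weak")) "D"
        else NA_character_,
      site_pos = plan$site_pos[r], support = plan$support[r],
      expected_disposition = switch(cl,
        intramolecular_stem = "intramolecular",
        mismap_decoy = "mismap_removed",
        if (plan$support[r] >= 2L) cl else "dropped_singleton"),
      stringsAsFactors = FALSE)
  }
  chim <- do.call(rbind, recs)
  class(chim) <- c("hyb_chimeras", class(chim))
  truth <- do.call(rbind, truth)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(hyb = file.path(dir, "chimeras.hyb"),
                  truth = file.path(dir, "truth.tsv"))
    write_chimeras(chim, files$hyb)
    utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(chimeras = chim, truth = truth, files = files)
}

#' Generate single (non-chimeric) read positions
#'
#' Samples single hits as uniform background over the mRNA targets plus a
#' configurable enrichment around hybrid start positions, and a per-mRNA
#' abundance table.
#'
#' @param cfg a [synthetic_config()].
#' @param ref a `synthetic_reference`.
#' @param hybrid_starts data.frame (`target_id`, `pos`); defaults to the
#'   target-fragment starts of the plan's mRNA-target interactions, or
#'   uniformly placed starts when none exist.
#' @return list `single_hits` (data.frame target_id, pos), `abundance`
#'   (data.frame target_id, abundance), `hybrid_starts`.
#' @export
generate_single_reads <- function(cfg, ref, hybrid_starts = NULL) {
  set.seed(cfg$seed + 2L)
  mrna_ids <- grep("^MRNA_T", names(ref$annotation$sequences), value = TRUE)
  lens <- nchar(ref$annotation$sequences[mrna_ids])
  if (is.null(hybrid_starts)) {
    hybrid_starts <- data.frame(
      target_id = sample(mrna_ids, 12L, replace = TRUE),
      pos = sample(200:800, 12L, replace = TRUE))
  }
  w <- cfg$single_window
  enr <- cfg$single_enrichment
  p_enriched <- enr / (enr + 1)
  n <- cfg$n_single_reads
  pick_enriched <- if (enr > 0) stats::runif(n) < p_enriched else rep(FALSE, n)
  target <- character(n); pos <- integer(n)
  for (k in seq_len(n)) {
    if (pick_enriched[k]) {
      h <- sample(nrow(hybrid_starts), 1)
      target[k] <- hybrid_starts$target_id[h]
      pos[k] <- hybrid_starts$pos[h] + sample(-w:w, 1)
    } else {
      target[k] <- sample(mrna_ids, 1)
      pos[k] <- sample.int(lens[[target[k]]], 1)
    }
  }
  keep <- pos >= 1 & pos <= lens[target]
  abundance <- data.frame(target_id = mrna_ids,
                          abundance = round(stats::rlnorm(length(mrna_ids),
                                                          5, 1)),
                          stringsAsFactors = FALSE)
  list(single_hits = data.frame(target_id = target[keep], pos = pos[keep],
                                stringsAsFactors = FALSE),
       abundance = abundance, hybrid_starts = hybrid_starts)
}
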