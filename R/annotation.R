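# Transcript models, snoRNA host placements, known methylation sites, and
# reference-database construction.
#
# Two coordinate systems are used. "Local" coordinates are 1-based
# positions along the unspliced gene span in transcript orientation (the
# coordinate system of the reference-database sequences and of all hyb
# fragment coordinates). "Spliced" transcript coordinates (exonic
# positions only) are used by tx_to_genome()/genome_to_tx().

.biotype_levels <- c("mRNA", "rRNA", "snoRNA", "tRNA", "other")

# genomic position -> local (unspliced, transcript-oriented) position
.g2local <- function(g, gene_start, gene_end, strand) {
  if (strand == "+") g - gene_start + 1L else gene_end - g + 1L
}

.make_transcript_model <- function(transcript_id, gene_id, chrom, strand,
                                   exons_g, cds_g = NULL, biotype = "other") {
  exons_g <- exons_g[order(exons_g[, 1]), , drop = FALSE]
  if (nrow(exons_g) > 1 &&
      any(exons_g[-1, 1] <= exons_g[-nrow(exons_g), 2])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  gene_start <- exons_g[1, 1]; gene_end <- exons_g[nrow(exons_g), 2]
  span_len <- gene_end - gene_start + 1L

  loc <- function(g) .g2local(g, gene_start, gene_end, strand)
  # exons in transcript orientation
  ex_local <- cbind(start = pmin(loc(exons_g[, 1]), loc(exons_g[, 2])),
                    end = pmax(loc(exons_g[, 1]), loc(exons_g[, 2])))
  ex_local <- ex_local[order(ex_local[, 1]), , drop = FALSE]
  # introns: exact gaps between adjacent exons
  introns_local <- NULL
  if (nrow(ex_local) > 1) {
    introns_local <- cbind(start = ex_local[-nrow(ex_local), 2] + 1L,
                           end = ex_local[-1, 1] - 1L)
  } else {
    introns_local <- matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("start", "end")))
  }
  cds_local <- NULL
  if (!is.null(cds_g)) {
    cds_local <- sort(c(loc(cds_g[1]), loc(cds_g[2])))
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, biotype = biotype,
    exons_g = exons_g, cds_g = cds_g,
    gene_start = gene_start, gene_end = gene_end, span_len = span_len,
    exons_local = ex_local, introns_local = introns_local,
    cds_local = cds_local,
    tx_len_spliced = sum(ex_local[, 2] - ex_local[, 1] + 1L)),
    class = "transcript_model")
}

#' Read reference annotation: GTF, sequences, and known methylation sites
#'
#' Builds an annotation set from a GTF-like file (exon and CDS features
#' with `gene_id`, `transcript_id` and `biotype` attributes), a FASTA of
#' per-transcript unspliced gene-span sequences (ids matching transcript
#' ids), and a TSV of known methylation sites
#' (`target_id, position, guide_family, box, source`; positions 1-based).
#'
#' snoRNA host placements are inferred by containment: a snoRNA gene whose
#' span lies inside an intron of another gene (same strand) is placed in
#' that host intron. A snoRNA overlapping a host exon gets no placement
#' (with a warning). A transcript named in the GTF but missing from the
#' FASTA is a hard error.
#'
#' @param gtf_path,fasta_path,sites_path input files; `sites_path` may be
#'   `NULL` for an empty site table.
#' @return an object of class `annotation_set`: list with `transcripts`
#'   (named list of transcript models), `sno_placements` (data.frame:
#'   snorna_id, host_tx, host_intron 1-based in transcript orientation),
#'   `known_sites` (data.frame) and `sequences` (named character, RNA).
#' @export
read_annotation <- function(gtf_path, fasta_path, sites_path = NULL) {
  gr <- rtracklayer::import(gtf_path)
  md <- S4Vectors::mcols(gr)
  biotype <- if ("biotype" %in% names(md)) md$biotype else md$gene_biotype
  if (is.null(biotype)) biotype <- rep("other", length(gr))
  type <- as.character(md$type)
  txid <- md$transcript_id

  fa <- Biostrings::readDNAStringSet(fasta_path)
  names(fa) <- sub("\\s.*$", "", names(fa))
  seqs <- vapply(as.character(fa), as_rna, character(1))
  names(seqs) <- names(fa)

  transcripts <- list()
  for (id in unique(stats::na.omit(txid))) {
    sel <- which(txid == id & type == "exon")
    if (!length(sel)) next
    ex <- cbind(GenomicRanges::start(gr)[sel], GenomicRanges::end(gr)[sel])
    strand <- as.character(GenomicRanges::strand(gr))[sel[1]]
    chrom <- as.character(GenomicRanges::seqnames(gr))[sel[1]]
    gid <- md$gene_id[sel[1]]
    bt <- biotype[sel[1]]
    if (!bt %in% .biotype_levels) bt <- "other"
    csel <- which(txid == id & type == "CDS")
    cds_g <- if (length(csel)) {
      c(min(GenomicRanges::start(gr)[csel]), max(GenomicRanges::end(gr)[csel]))
    } else NULL
    tm <- .make_transcript_model(id, gid, chrom, strand, ex, cds_g, bt)
    if (!id %in% names(seqs)) {
      stop("missing sequence for transcript ", id)
    }
    if (nchar(seqs[[id]]) != tm$span_len) {
      stop("sequence length for ", id, " (", nchar(seqs[[id]]),
           ") does not match gene span (", tm$span_len, ")")
    }
    transcripts[[id]] <- tm
  }

  # snoRNA placements by containment in a host intron
  plc <- list()
  snos <- Filter(function(t) t$biotype == "snoRNA", transcripts)
  hosts <- Filter(function(t) nrow(t$introns_local) > 0, transcripts)
  for (sno in snos) {
    placed <- FALSE
    for (host in hosts) {
      if (host$transcript_id == sno$transcript_id) next
      if (host$chrom != sno$chrom || host$strand != sno$strand) next
      if (sno$gene_start < host$gene_start || sno$gene_end > host$gene_end) next
      sl <- sort(c(.g2local(sno$gene_start, host$gene_start, host$gene_end,
                            host$strand),
                   .g2local(sno$gene_end, host$gene_start, host$gene_end,
                            host$strand)))
      idx <- which(host$introns_local[, 1] <= sl[1] &
                     host$introns_local[, 2] >= sl[2])
      if (length(idx) == 1L) {
        plc[[length(plc) + 1L]] <- data.frame(
          snorna_id = sno$transcript_id, host_tx = host$transcript_id,
          host_intron = idx, sno_local_start = sl[1], sno_local_end = sl[2],
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      # inside host span but crossing/overlapping an exon
      ov_ex <- any(host$exons_local[, 1] <= sl[2] &
                     host$exons_local[, 2] >= sl[1])
      if (ov_ex) {
        warning("snoRNA ", sno$transcript_id, " overlaps an exon of host ",
                host$transcript_id, "; no placement assigned")
        placed <- TRUE
        break
      }
    }
  }
  sno_placements <- if (length(plc)) do.call(rbind, plc) else
    data.frame(snorna_id = character(0), host_tx = character(0),
               host_intron = integer(0), sno_local_start = integer(0),
               sno_local_end = integer(0), stringsAsFactors = FALSE)

  known_sites <- read_known_sites(sites_path, seqs)

  structure(list(transcripts = transcripts, sno_placements = sno_placements,
                 known_sites = known_sites, sequences = seqs),
            class = "annotation_set")
}

#' Read a known-methylation-site table
#'
#' @param path TSV with header `target_id, position, guide_family, box,
#'   source` (1-based positions), or `NULL` for an empty table.
#' @param sequences optional named sequences used to bounds-check positions.
#' @return data.frame of known sites.
#' @export
read_known_sites <- function(path, sequences = NULL) {
  if (is.null(path)) {
    return(data.frame(target_id = character(0), position = integer(0),
                      guide_family = character(0), box = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  ks <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("target_id", "position", "guide_family") %in% names(ks)))
  if (!"box" %in% names(ks)) ks$box <- "unknown"
  if (!"source" %in% names(ks)) ks$source <- ""
  ks$position <- as.integer(ks$position)
  if (anyDuplicated(ks[, c("target_id", "position", "guide_family")])) {
    stop("duplicate (target_id, position, guide_family) rows in site table")
  }
  if (!is.null(sequences)) {
    known <- ks$target_id %in% names(sequences)
    bad <- known & (ks$position < 1L |
                      ks$position > nchar(sequences[ks$target_id]))
    if (any(bad)) stop("site position outside target bounds for ",
                       paste(ks$target_id[bad], collapse = ", "))
  }
  ks
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$transcripts), "transcripts,",
      nrow(x$sno_placements), "snoRNA host placements,",
      nrow(x$known_sites), "known sites\n")
  bt <- table(vapply(x$transcripts, function(t) t$biotype, character(1)))
  cat(" biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Build the alignment reference database
#'
#' snoRNA entries are extended by `flank` nt on each side (clipped at the
#' host gene bounds; standalone snoRNAs are not extended) and the extended
#' snoRNA span is masked to `N` in the host-gene sequence whenever a
#' placement exists.
#'
#' @param annotation an `annotation_set`.
#' @param flank extension, nt, each side.
#' @return list of class `reference_db`: `sequences` (named character) and
#'   `meta` (data.frame: id, biotype, ext_left, ext_right — the realised
#'   extensions after clipping).
#' @export
build_reference_db <- function(annotation, flank = 20L) {
  stopifnot(inherits(annotation, "annotation_set"), flank >= 0L)
  seqs <- annotation$sequences
  tx <- annotation$transcripts
  plc <- annotation$sno_placements
  out <- seqs[names(tx)]
  ext_left <- stats::setNames(integer(length(tx)), names(tx))
  ext_right <- stats::setNames(integer(length(tx)), names(tx))
  for (k in seq_len(nrow(plc))) {
    sid <- plc$snorna_id[k]; hid <- plc$host_tx[k]
    host_seq <- seqs[[hid]]
    ls <- plc$sno_local_start[k]; le <- plc$sno_local_end[k]
    s2 <- max(1L, ls - flank)
    e2 <- min(nchar(host_seq), le + flank)
    out[[sid]] <- substring(host_seq, s2, e2)
    ext_left[[sid]] <- ls - s2
    ext_right[[sid]] <- e2 - le
    # mask the extended span out of the host
    masked <- out[[hid]]
    substring(masked, s2, e2) <- strrep("N", e2 - s2 + 1L)
    out[[hid]] <- masked
  }
  meta <- data.frame(
    id = names(tx),
    biotype = vapply(tx, function(t) t$biotype, character(1)),
    ext_left = ext_left[names(tx)], ext_right = ext_right[names(tx)],
    stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  structure(list(sequences = out, meta = meta, flank = as.integer(flank)),
            class = "reference_db")
}

#' Write a reference database (or any named sequence set) as FASTA
#' @param db a `reference_db` or named character vector of sequences.
#' @param path output FASTA path.
#' @export
write_reference_fasta <- function(db, path) {
  seqs <- if (inherits(db, "reference_db")) db$sequences else db
  x <- Biostrings::DNAStringSet(gsub("U", "T", unlist(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Project a spliced-transcript interval onto the genome
#'
#' Strand- and exon-aware: an interval crossing an exon junction maps to
#' one genomic interval per exon touched.
#'
#' @param interval `c(start, end)` in 1-based spliced transcript
#'   coordinates.
#' @param tx a transcript model from an `annotation_set`.
#' @return data.frame (chrom, start, end, strand), in transcript order.
#' @export
tx_to_genome <- function(interval, tx) {
  s <- interval[1]; e <- interval[2]
  if (s < 1L || e > tx$tx_len_spliced || s > e) {
    stop("interval out of transcript range")
  }
  # exons in transcript orientation with genomic coordinates
  ex <- tx$exons_g
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  w <- ex[, 2] - ex[, 1] + 1L
  offs <- cumsum(c(0L, w[-length(w)]))  # spliced offset before each exon
  res <- list()
  for (k in seq_len(nrow(ex))) {
    lo <- offs[k] + 1L; hi <- offs[k] + w[k]
    if (e < lo || s > hi) next
    a <- max(s, lo) - offs[k]   # 1-based within exon (transcript orientation)
    b <- min(e, hi) - offs[k]
    if (tx$strand == "+") {
      gs <- ex[k, 1] + a - 1L; ge <- ex[k, 1] + b - 1L
    } else {
      gs <- ex[k, 2] - b + 1L; ge <- ex[k, 2] - a + 1L
    }
    res[[length(res) + 1L]] <- data.frame(
      chrom = tx$chrom, start = gs, end = ge, strand = tx$strand,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Project genomic intervals back onto spliced transcript coordinates
#'
#' Inverse of [tx_to_genome()]: every genomic interval must lie within the
#' transcript's exons; the union of the projected pieces is returned as a
#' single merged interval when contiguous.
#'
#' @param gintervals data.frame with `start`, `end` genomic columns.
#' @param tx a transcript model.
#' @return `c(start, end)` in spliced transcript coordinates (contiguous
#'   input), or a two-column matrix of intervals otherwise.
#' @export
genome_to_tx <- function(gintervals, tx) {
  ex <- tx$exons_g
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  w <- ex[, 2] - ex[, 1] + 1L
  offs <- cumsum(c(0L, w[-length(w)]))
  pieces <- list()
  for (r in seq_len(nrow(gintervals))) {
    gs <- gintervals$start[r]; ge <- gintervals$end[r]
    hit <- which(ex[, 1] <= gs & ex[, 2] >= ge)
    if (length(hit) != 1L) stop("genomic interval not contained in one exon")
    k <- hit
    if (tx$strand == "+") {
      a <- gs - ex[k, 1] + 1L; b <- ge - ex[k, 1] + 1L
    } else {
      a <- ex[k, 2] - ge + 1L; b <- ex[k, 2] - gs + 1L
    }
    pieces[[r]] <- c(offs[k] + a, offs[k] + b)
  }
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  # merge contiguous pieces
  merged <- list(m[1, ])
  if (nrow(m) > 1) for (r in 2:nrow(m)) {
    last <- merged[[length(merged)]]
    if (m[r, 1] == last[2] + 1L) {
      merged[[length(merged)]] <- c(last[1], m[r, 2])
    } else merged[[length(merged) + 1L]] <- m[r, ]
  }
  if (length(merged) == 1L) merged[[1]] else do.call(rbind, merged)
}

#' Export genomic intervals as BED6
#' @param gintervals data.frame (chrom, start, end, strand) in 1-based
#'   closed coordinates; converted to BED half-open.
#' @param names,scores optional BED name/score columns.
#' @param path output path.
#' @export
export_bed <- function(gintervals, path, names = ".", scores = 0L) {
  df <- data.frame(gintervals$chrom, gintervals$start - 1L, gintervals$end,
                   names, scores, gintervals$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
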