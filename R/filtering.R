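# Reduction of raw chimeras to stable, reproducible, correctly-mapped
# interaction clusters.

# biotype of a transcript id under an annotation_set ("unknown" if absent)
.biotype_of <- function(ids, annotation) {
  bt <- vapply(annotation$transcripts, function(t) t$biotype, character(1))
  out <- bt[ids]
  out[is.na(out)] <- "unknown"
  unname(out)
}

#' Split chimeras into intermolecular and intramolecular (snoRNA stems)
#'
#' Intramolecular records are those whose two fragments map to the same
#' snoRNA transcript (internal stem structures). Records citing an
#' unknown transcript id are routed to a quarantine set. The three sets
#' partition the input.
#'
#' @param records chimera data.frame ([read_chimeras()]).
#' @param annotation an `annotation_set` used to resolve biotypes.
#' @return list `inter`, `intra`, `quarantine` (chimera data.frames).
#' @export
filter_intramolecular <- function(records, annotation) {
  b1 <- .biotype_of(records$tx1, annotation)
  b2 <- .biotype_of(records$tx2, annotation)
  unknown <- b1 == "unknown" | b2 == "unknown"
  intra <- !unknown & records$tx1 == records$tx2 & b1 == "snoRNA"
  list(inter = records[!unknown & !intra, , drop = FALSE],
       intra = records[intra, , drop = FALSE],
       quarantine = records[unknown, , drop = FALSE])
}

# union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster chimeras into reproducible interactions
#'
#' Single-linkage clustering: two records link iff their fragment-1
#' intervals overlap by at least `min_overlap` nt on the same transcript
#' AND their fragment-2 intervals overlap likewise. Clusters supported by
#' fewer than `min_support` reads are flagged non-reproducible.
#'
#' Records are first oriented so that comparable fragments are compared
#' (the fragment pair is treated as unordered: a record with the two
#' fragments in the opposite read order joins the same cluster).
#'
#' @param records intermolecular chimera data.frame.
#' @param min_support minimum member count for the reproducible flag.
#' @param min_overlap minimum fragment overlap, nt.
#' @param distinct_sequences if `TRUE`, support counts distinct read
#'   sequences rather than distinct read ids (PCR-duplicate-conservative).
#' @return data.frame of class `interaction_clusters`: one row per
#'   cluster with `cluster_id`, transcripts, representative (union) spans,
#'   `support`, `best_dG` (minimum member energy, `NA` if absent),
#'   `reproducible`, `pair_type`, and `members` (comma-joined read ids).
#'   The input row indices of each cluster are attached as
#'   `attr(x, "member_rows")`.
#' @export
cluster_reproducible <- function(records, min_support = 2L, min_overlap = 1L,
                                 distinct_sequences = FALSE) {
  n <- nrow(records)
  if (n == 0L) {
    out <- data.frame(cluster_id = character(0), tx1 = character(0),
                      t1_begin = integer(0), t1_end = integer(0),
                      tx2 = character(0), t2_begin = integer(0),
                      t2_end = integer(0), support = integer(0),
                      best_dG = numeric(0), reproducible = logical(0),
                      members = character(0), stringsAsFactors = FALSE)
    attr(out, "member_rows") <- list()
    class(out) <- c("interaction_clusters", class(out))
    return(out)
  }
  # canonical fragment orientation: lexicographically smaller (tx, begin)
  # first, so read order does not affect clustering
  key1 <- paste0(records$tx1, ":", records$t1_begin)
  key2 <- paste0(records$tx2, ":", records$t2_begin)
  swap <- pmin(key1, key2) != key1
  a_tx <- ifelse(swap, records$tx2, records$tx1)
  a_s <- ifelse(swap, records$t2_begin, records$t1_begin)
  a_e <- ifelse(swap, records$t2_end, records$t1_end)
  b_tx <- ifelse(swap, records$tx1, records$tx2)
  b_s <- ifelse(swap, records$t1_begin, records$t2_begin)
  b_e <- ifelse(swap, records$t1_end, records$t2_end)

  parent <- seq_len(n)
  grp <- split(seq_len(n), paste(a_tx, b_tx, sep = "\t"))
  for (idx in grp) {
    if (length(idx) < 2L) next
    ir_a <- IRanges::IRanges(a_s[idx], a_e[idx])
    ir_b <- IRanges::IRanges(b_s[idx], b_e[idx])
    ha <- IRanges::findOverlaps(ir_a, minoverlap = min_overlap,
                                drop.self = TRUE, drop.redundant = TRUE)
    hb <- IRanges::findOverlaps(ir_b, minoverlap = min_overlap,
                                drop.self = TRUE, drop.redundant = TRUE)
    ka <- paste(S4Vectors::queryHits(ha), S4Vectors::subjectHits(ha))
    kb <- paste(S4Vectors::queryHits(hb), S4Vectors::subjectHits(hb))
    both <- intersect(ka, kb)
    for (e in both) {
      ij <- as.integer(strsplit(e, " ")[[1]])
      ri <- .uf_find(parent, idx[ij[1]]); rj <- .uf_find(parent, idx[ij[2]])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  # deterministic cluster order: by transcripts then coordinates of the
  # 5'-most member, independent of input permutation
  comps <- split(seq_len(n), root)
  rep_key <- vapply(comps, function(ix) {
    paste(a_tx[ix[1]], b_tx[ix[1]],
          sprintf("%09d", min(a_s[ix])), sprintf("%09d", min(b_s[ix])))
  }, character(1))
  comps <- comps[order(rep_key)]
  rows <- lapply(seq_along(comps), function(k) {
    ix <- comps[[k]]
    supp <- if (distinct_sequences) length(unique(records$read_seq[ix]))
            else length(unique(records$read_id[ix]))
    data.frame(
      cluster_id = sprintf("C%05d", k),
      tx1 = a_tx[ix[1]], t1_begin = min(a_s[ix]), t1_end = max(a_e[ix]),
      tx2 = b_tx[ix[1]], t2_begin = min(b_s[ix]), t2_end = max(b_e[ix]),
      support = supp,
      best_dG = if (all(is.na(records$energy[ix]))) NA_real_
                else min(records$energy[ix], na.rm = TRUE),
      reproducible = supp >= min_support,
      members = paste(sort(records$read_id[ix]), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "member_rows") <- stats::setNames(comps, out$cluster_id)
  class(out) <- c("interaction_clusters", class(out))
  out
}

#' Remove chimeras whose non-snoRNA fragment mismaps to U3 or rRNA
#'
#' Scoped to snoRNA-X records where X is neither a snoRNA nor an rRNA
#' (snoRNA-rRNA and snoRNA-snoRNA hybrids are kept unexamined). The X
#' fragment sequence is locally aligned against each decoy; the record is
#' removed iff some decoy alignment reaches `min_identity` over at least
#' `min_cov` of the fragment length.
#'
#' @param records chimera data.frame.
#' @param decoy_sequences named character vector of decoy sequences (must
#'   contain the U3 and rRNA sequences); empty set is an error.
#' @param annotation an `annotation_set` for biotype resolution.
#' @param min_identity minimum alignment identity (fraction).
#' @param min_cov minimum fraction of the fragment covered.
#' @return list `kept`, `removed` (partition of the input) and `report`
#'   (data.frame: read_id, applied, decoy, identity, coverage, removed).
#' @export
filter_mismap <- function(records, decoy_sequences, annotation,
                          min_identity = 0.75, min_cov = 0.7) {
  if (length(decoy_sequences) == 0L) {
    stop("empty decoy set: the mismap filter must not silently no-op")
  }
  n <- nrow(records)
  b1 <- .biotype_of(records$tx1, annotation)
  b2 <- .biotype_of(records$tx2, annotation)
  # which side is the snoRNA; X = the other side
  sno1 <- b1 == "snoRNA"
  xbio <- ifelse(sno1, b2, b1)
  applies <- (sno1 | b2 == "snoRNA") & !(xbio %in% c("snoRNA", "rRNA"))
  removed <- logical(n)
  rep_rows <- vector("list", n)
  decoys <- Biostrings::DNAStringSet(gsub("U", "T", decoy_sequences))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in seq_len(n)) {
    if (!applies[i]) {
      rep_rows[[i]] <- data.frame(read_id = records$read_id[i],
                                  applied = FALSE, decoy = NA_character_,
                                  identity = NA_real_, coverage = NA_real_,
                                  removed = FALSE, stringsAsFactors = FALSE)
      next
    }
    xs <- if (sno1[i]) {
      substring(records$read_seq[i], records$r2_begin[i], records$r2_end[i])
    } else {
      substring(records$read_seq[i], records$r1_begin[i], records$r1_end[i])
    }
    xs_dna <- gsub("U", "T", toupper(xs))
    flen <- nchar(xs_dna)
    best_id <- 0; best_cov <- 0; best_decoy <- NA_character_
    for (d in seq_along(decoys)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(xs_dna), decoys[[d]], type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      aw <- Biostrings::nchar(al)
      if (aw == 0) next
      idy <- Biostrings::pid(al) / 100
      cov <- Biostrings::width(Biostrings::pattern(al)) / flen
      if (idy >= min_identity && cov >= min_cov) {
        best_id <- idy; best_cov <- cov
        best_decoy <- names(decoy_sequences)[d]
        break
      }
      if (idy > best_id) { best_id <- idy; best_cov <- cov }
    }
    removed[i] <- !is.na(best_decoy)
    rep_rows[[i]] <- data.frame(read_id = records$read_id[i], applied = TRUE,
                                decoy = best_decoy, identity = best_id,
                                coverage = best_cov, removed = removed[i],
                                stringsAsFactors = FALSE)
  }
  report <- if (n) do.call(rbind, rep_rows) else
    data.frame(read_id = character(0), applied = logical(0),
               decoy = character(0), identity = numeric(0),
               coverage = numeric(0), removed = logical(0),
               stringsAsFactors = FALSE)
  list(kept = records[!removed, , drop = FALSE],
       removed = records[removed, , drop = FALSE],
       report = report)
}

#' Tabulate interaction clusters by biotype pair
#'
#' @param clusters an `interaction_clusters` data.frame.
#' @param annotation an `annotation_set`.
#' @return data.frame (biotype1, biotype2, count, fraction); snoRNA is
#'   reported as biotype1 where one side is a snoRNA; fractions sum to 1.
#' @export
summarize_pair_types <- function(clusters, annotation) {
  if (nrow(clusters) == 0L) {
    return(data.frame(biotype1 = character(0), biotype2 = character(0),
                      count = integer(0), fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  b1 <- .biotype_of(clusters$tx1, annotation)
  b2 <- .biotype_of(clusters$tx2, annotation)
  swap <- b2 == "snoRNA" & b1 != "snoRNA"
  pt1 <- ifelse(swap, b2, b1)
  pt2 <- ifelse(swap, b1, b2)
  tab <- as.data.frame(table(biotype1 = pt1, biotype2 = pt2),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(biotype1 = tab$biotype1, biotype2 = tab$biotype2,
                    count = as.integer(tab$Freq),
                    fraction = tab$Freq / nrow(clusters),
                    stringsAsFactors = FALSE)
  out[order(-out$count), , drop = FALSE]
}
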