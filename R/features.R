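# Target-feature annotation: mRNA feature assignment, host-intron
# relationships, branch-point windows, intron metaprofiles, interval
# overlap/closest tables, and hybrid-vs-single-read comparisons.
#
# All intervals here are in local (unspliced, transcript-oriented)
# coordinates of the target gene, as produced by the reference database.

.FEATURE_LEVELS <- c("CDS", "UTR5", "UTR3", "intron", "exon_noncoding",
                     "intergenic")

# feature intervals of a transcript model, local coordinates
.feature_intervals <- function(tx) {
  ex <- tx$exons_local
  feats <- list()
  if (tx$biotype == "mRNA" && !is.null(tx$cds_local)) {
    cs <- tx$cds_local[1]; ce <- tx$cds_local[2]
    for (k in seq_len(nrow(ex))) {
      s <- ex[k, 1]; e <- ex[k, 2]
      if (e < cs) feats[[length(feats) + 1L]] <- c("UTR5", s, e)
      else if (s > ce) feats[[length(feats) + 1L]] <- c("UTR3", s, e)
      else {
        if (s < cs) feats[[length(feats) + 1L]] <- c("UTR5", s, cs - 1L)
        feats[[length(feats) + 1L]] <- c("CDS", max(s, cs), min(e, ce))
        if (e > ce) feats[[length(feats) + 1L]] <- c("UTR3", ce + 1L, e)
      }
    }
  } else {
    for (k in seq_len(nrow(ex))) {
      feats[[length(feats) + 1L]] <- c("exon_noncoding", ex[k, 1], ex[k, 2])
    }
  }
  for (k in seq_len(nrow(tx$introns_local))) {
    feats[[length(feats) + 1L]] <- c("intron", tx$introns_local[k, 1],
                                     tx$introns_local[k, 2])
  }
  data.frame(feature = vapply(feats, `[`, "", 1),
             start = as.integer(vapply(feats, `[`, "", 2)),
             end = as.integer(vapply(feats, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Assign an mRNA feature label to a target interval
#'
#' Majority-overlap assignment over the transcript's feature intervals
#' (CDS, UTR5, UTR3, intron, exon_noncoding), with ties broken by the
#' fixed precedence CDS > UTR5 > UTR3 > intron > exon_noncoding. An
#' interval with no resolvable transcript or no overlap is `intergenic`.
#'
#' @param target_interval `c(start, end)` local coordinates.
#' @param tx a transcript model (or `NULL` -> `intergenic`).
#' @return one of `"CDS"`, `"UTR5"`, `"UTR3"`, `"intron"`,
#'   `"exon_noncoding"`, `"intergenic"`.
#' @export
assign_feature <- function(target_interval, tx) {
  if (is.null(tx)) return("intergenic")
  fi <- .feature_intervals(tx)
  ov <- pmin(target_interval[2], fi$end) - pmax(target_interval[1], fi$start) + 1L
  ov[ov < 0L] <- 0L
  by_feat <- tapply(ov, factor(fi$feature, levels = .FEATURE_LEVELS), sum)
  by_feat[is.na(by_feat)] <- 0
  if (all(by_feat == 0)) return("intergenic")
  # which.max on the precedence-ordered factor resolves ties by precedence
  names(by_feat)[which.max(by_feat)]
}

#' Relation of a target interval to a snoRNA's host gene
#'
#' `host_intron_cis` iff the interval overlaps the snoRNA's own host
#' intron; `same_host_gene_trans` iff it lies in the host gene but in
#' another intron or exon; `non_host` otherwise (including snoRNAs with
#' no placement, with a warning).
#'
#' @param snorna_id snoRNA id.
#' @param target_tx_id target transcript id.
#' @param target_interval `c(start, end)` local coordinates on the target.
#' @param annotation an `annotation_set`.
#' @return one of `"host_intron_cis"`, `"same_host_gene_trans"`,
#'   `"non_host"`.
#' @export
host_relation <- function(snorna_id, target_tx_id, target_interval,
                          annotation) {
  plc <- annotation$sno_placements
  row <- plc[plc$snorna_id == snorna_id, , drop = FALSE]
  if (!nrow(row)) {
    warning("snoRNA ", snorna_id, " has no host placement")
    return("non_host")
  }
  if (target_tx_id != row$host_tx[1]) return("non_host")
  host <- annotation$transcripts[[row$host_tx[1]]]
  intr <- host$introns_local[row$host_intron[1], ]
  if (target_interval[1] <= intr[2] && target_interval[2] >= intr[1]) {
    "host_intron_cis"
  } else {
    "same_host_gene_trans"
  }
}

#' Branch-point window membership
#'
#' True iff the interval overlaps the estimated branch-point region
#' `window[1]`..`window[2]` nt upstream of the intron's 3' end
#' (transcript orientation; default 20-50 nt).
#'
#' @param target_interval `c(start, end)` local coordinates.
#' @param intron `c(start, end)` of the intron, same coordinates.
#' @param window `c(near, far)` distances upstream of the 3' splice site.
#' @return logical.
#' @export
branchpoint_window <- function(target_interval, intron, window = c(20L, 50L)) {
  w_start <- intron[2] - window[2]
  w_end <- intron[2] - window[1]
  target_interval[1] <= w_end && target_interval[2] >= w_start
}

#' Coverage metaprofile over the last N intron positions
#'
#' Positions are indexed -last_n..-1 relative to the intron 3' end;
#' coverage at a position counts the fragments overlapping it. Introns
#' shorter than `last_n` contribute only their covered suffix.
#'
#' @param fragments data.frame with `intron_id`, `start`, `end` (local
#'   coordinates on the intron's transcript).
#' @param introns data.frame with `intron_id`, `start`, `end`.
#' @param last_n profile length.
#' @return integer vector of length `last_n`, names `-last_n`..`-1`.
#' @export
intron_metaprofile <- function(fragments, introns, last_n = 1000L) {
  prof <- integer(last_n)
  names(prof) <- as.character(seq(-last_n, -1L))
  for (r in seq_len(nrow(fragments))) {
    ir <- introns[introns$intron_id == fragments$intron_id[r], , drop = FALSE]
    if (!nrow(ir)) next
    e3 <- ir$end[1]
    lo <- max(fragments$start[r], ir$start[1], e3 - last_n + 1L)
    hi <- min(fragments$end[r], e3)
    if (lo > hi) next
    # offsets relative to the 3' end: position p -> p - e3 (in -last_n..-1 + 0)
    off <- (lo:hi) - e3
    off <- off[off >= -last_n & off <= -1L]
    idx <- off + last_n + 1L
    prof[idx] <- prof[idx] + 1L
  }
  prof
}

#' Interval overlap pairs and nearest-neighbour table
#'
#' For two sets of intervals/points: all overlapping pairs (>= 1 nt,
#' unstranded) and, for every `a`, the nearest `b` with signed distance
#' (negative when `b` lies 5' of `a`); ties go to the 5'-most `b`.
#'
#' @param a_set,b_set data.frames with `start`, `end` columns (points:
#'   `start == end`); an optional `id` column is carried through.
#' @return list `overlaps` (data.frame a, b of row indices) and `closest`
#'   (data.frame a, b, distance).
#' @export
interval_overlap_and_closest <- function(a_set, b_set) {
  ia <- IRanges::IRanges(a_set$start, a_set$end)
  ib <- IRanges::IRanges(b_set$start, b_set$end)
  hits <- IRanges::findOverlaps(ia, ib, minoverlap = 1L)
  overlaps <- data.frame(a = S4Vectors::queryHits(hits),
                         b = S4Vectors::subjectHits(hits))
  n_a <- nrow(a_set); n_b <- nrow(b_set)
  closest <- data.frame(a = seq_len(n_a), b = NA_integer_,
                        distance = NA_integer_)
  if (n_b > 0) for (i in seq_len(n_a)) {
    gap <- ifelse(b_set$start > a_set$end[i], b_set$start - a_set$end[i],
                  ifelse(b_set$end < a_set$start[i],
                         b_set$end - a_set$start[i], 0L))
    best <- min(abs(gap))
    cand <- which(abs(gap) == best)
    j <- cand[order(b_set$start[cand])][1]   # 5'-most b on ties
    closest$b[i] <- j
    closest$distance[i] <- gap[j]
  }
  list(overlaps = overlaps, closest = closest)
}

#' Single-hit metaprofile around hybrid starts and count correlations
#'
#' (a) Coverage of single (non-chimeric) hits in a window around hybrid
#' start positions, summed over hybrids; (b) correlations between
#' per-mRNA hybrid counts and single-hit counts, and between hybrid
#' counts and mRNA abundance: Pearson on log10(x+1)-transformed counts,
#' Spearman on raw counts.
#'
#' @param hybrid_starts data.frame with `target_id`, `pos`.
#' @param single_hits data.frame with `target_id`, `pos` (one row per
#'   hit; multiple hits at one position are repeated rows).
#' @param abundance optional data.frame with `target_id`, `abundance`.
#' @param window half-width (nt) of the metaprofile.
#' @return list `metaprofile` (integer vector, names -window..window),
#'   `correlations` (data.frame: comparison, n, pearson_log10,
#'   spearman; `NA` with fewer than 3 mRNAs), `per_mrna` (the count
#'   table).
#' @export
hybrid_vs_single_stats <- function(hybrid_starts, single_hits,
                                   abundance = NULL, window = 200L) {
  offs <- seq(-window, window)
  prof <- integer(length(offs))
  names(prof) <- as.character(offs)
  sh <- split(single_hits$pos, single_hits$target_id)
  for (r in seq_len(nrow(hybrid_starts))) {
    hp <- sh[[hybrid_starts$target_id[r]]]
    if (is.null(hp)) next
    d <- hp - hybrid_starts$pos[r]
    d <- d[d >= -window & d <= window]
    if (length(d)) {
      t_ <- table(d)
      idx <- as.integer(names(t_)) + window + 1L
      prof[idx] <- prof[idx] + as.integer(t_)
    }
  }
  ids <- sort(unique(c(hybrid_starts$target_id, single_hits$target_id,
                       if (!is.null(abundance)) abundance$target_id)))
  per <- data.frame(
    target_id = ids,
    hybrids = as.integer(table(factor(hybrid_starts$target_id, ids))),
    singles = as.integer(table(factor(single_hits$target_id, ids))),
    stringsAsFactors = FALSE)
  if (!is.null(abundance)) {
    per$abundance <- abundance$abundance[match(ids, abundance$target_id)]
    per$abundance[is.na(per$abundance)] <- 0
  }
  corr_row <- function(x, y, what) {
    n <- length(x)
    if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(comparison = what, n = n,
                        pearson_log10 = NA_real_, spearman = NA_real_))
    }
    data.frame(comparison = what, n = n,
               pearson_log10 = stats::cor(log10(x + 1), log10(y + 1)),
               spearman = stats::cor(x, y, method = "spearman"))
  }
  correlations <- corr_row(per$hybrids, per$singles, "hybrids_vs_singles")
  if (!is.null(abundance)) {
    correlations <- rbind(correlations,
                          corr_row(per$hybrids, per$abundance,
                                   "hybrids_vs_abundance"))
  }
  list(metaprofile = prof, correlations = correlations, per_mrna = per)
}
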