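# Box C/D/C'/D' motif location on snoRNA sequences and guide geometry:
# the pairing state of the snoRNA nucleotides 1..16 upstream of box D or
# box D', mapped through a chimera's fragment alignment into a predicted
# duplex. Offset k is the k-th nucleotide 5' of the box's first residue
# (offset 1 immediately adjacent); the canonical +5 rule places the
# methylated target nucleotide opposite offset 5.

.BOX_C_PATTERN <- c("R", "U", "G", "A", "U", "G", "A")  # RUGAUGA, R = A/G
.BOX_D_PATTERN <- c("C", "U", "G", "A")                 # CUGA

# mismatches of seq window vs pattern with IUPAC R support
.box_mismatches <- function(ch, start, pattern) {
  w <- ch[start:(start + length(pattern) - 1L)]
  sum(vapply(seq_along(pattern), function(i) {
    p <- pattern[i]
    if (p == "R") !(w[i] %in% c("A", "G")) else w[i] != p
  }, logical(1)))
}

# best motif match in [from, to] (start positions); returns start or NA
.scan_box <- function(ch, pattern, from, to, max_mm, tie = c("5prime", "3prime")) {
  tie <- match.arg(tie)
  to <- min(to, length(ch) - length(pattern) + 1L)
  if (from > to) return(NA_integer_)
  starts <- from:to
  mm <- vapply(starts, function(s) .box_mismatches(ch, s, pattern), numeric(1))
  ok <- which(mm <= max_mm)
  if (!length(ok)) return(NA_integer_)
  best <- ok[mm[ok] == min(mm[ok])]
  if (tie == "5prime") starts[best[1]] else starts[best[length(best)]]
}

#' Locate box C, D, C' and D' motifs on a snoRNA sequence
#'
#' Box C is the best RUGAUGA match (at most one mismatch) in the 5' third
#' of the sequence (ties: 5'-most); box D is an exact CUGA in the last 20
#' nt (ties: 3'-most). The internal C'/D' elements are searched between
#' box C and box D: box C' as an RUGAUGA-like match (<=1 mismatch) in the
#' 3' half of the internal region, box D' as a CUGA-like match
#' (<=1 mismatch) 5' of box C' (ties: 3'-most). Absent motifs are `NA`.
#' Curated annotations, when available, should override detection (see
#' [read_box_annotation()]).
#'
#' @param seq snoRNA sequence (50-350 nt).
#' @param snorna_id optional id stored in the result.
#' @param boxC_mm,boxDprime_mm mismatch allowances.
#' @return object of class `box_annotation`: list with `snorna_id`,
#'   1-based spans `boxC` (7 nt), `boxD` (4 nt), `boxCprime`, `boxDprime`
#'   (or `NA`), and `provenance = "detected"`.
#' @export
detect_boxes <- function(seq, snorna_id = NA_character_,
                         boxC_mm = 1L, boxDprime_mm = 1L) {
  seq <- as_rna(seq, allow_empty = FALSE)
  L <- nchar(seq)
  if (L < 50L || L > 350L) {
    warning("snoRNA length ", L, " outside the usual 50-350 nt range")
  }
  ch <- .chars(seq)
  cstart <- .scan_box(ch, .BOX_C_PATTERN, 1L, floor(L / 3), boxC_mm, "5prime")
  dstart <- .scan_box(ch, .BOX_D_PATTERN, max(1L, L - 19L), L - 3L, 0L, "3prime")
  if (is.na(dstart)) {
    warning("no box D (CUGA) candidate in the last 20 nt",
            if (!is.na(snorna_id)) paste0(" of ", snorna_id) else "",
            "; snoRNA unusable for D-box classification")
  }
  cpstart <- NA_integer_; dpstart <- NA_integer_
  int_from <- if (!is.na(cstart)) cstart + 7L else floor(L / 3) + 1L
  int_to <- if (!is.na(dstart)) dstart - 1L else L - 20L
  if (int_to - int_from + 1L >= 11L) {
    half <- int_from + floor((int_to - int_from) / 2)
    cpstart <- .scan_box(ch, .BOX_C_PATTERN, half, int_to - 6L, boxC_mm,
                         "5prime")
    dp_to <- if (!is.na(cpstart)) cpstart - 1L else int_to - 3L
    dpstart <- .scan_box(ch, .BOX_D_PATTERN, int_from, dp_to - 3L,
                         boxDprime_mm, "3prime")
  }
  span <- function(s, len) if (is.na(s)) c(NA_integer_, NA_integer_) else
    c(s, s + len - 1L)
  structure(list(snorna_id = snorna_id,
                 boxC = span(cstart, 7L), boxD = span(dstart, 4L),
                 boxCprime = span(cpstart, 7L), boxDprime = span(dpstart, 4L),
                 provenance = "detected"),
            class = "box_annotation")
}

#' Construct a curated box annotation
#' @param snorna_id snoRNA id.
#' @param boxC_start,boxD_start,boxDprime_start,boxCprime_start 1-based
#'   motif start positions (`NA` when absent); box C/C' are 7 nt, box D/D'
#'   4 nt.
#' @return a `box_annotation` with `provenance = "annotated"`.
#' @export
box_annotation <- function(snorna_id, boxC_start = NA, boxD_start = NA,
                           boxDprime_start = NA, boxCprime_start = NA) {
  span <- function(s, len) if (is.na(s)) c(NA_integer_, NA_integer_) else
    c(as.integer(s), as.integer(s) + len - 1L)
  structure(list(snorna_id = snorna_id,
                 boxC = span(boxC_start, 7L), boxD = span(boxD_start, 4L),
                 boxCprime = span(boxCprime_start, 7L),
                 boxDprime = span(boxDprime_start, 4L),
                 provenance = "annotated"),
            class = "box_annotation")
}

#' Read / write curated box annotations
#'
#' TSV with columns `snorna_id, boxC_start, boxD_start, boxDprime_start,
#' boxCprime_start` (1-based starts, `NA` when absent).
#'
#' @param path file path.
#' @return `read_box_annotation` returns a named list of `box_annotation`
#'   objects (names = snoRNA ids).
#' @export
read_box_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(k) {
    box_annotation(df$snorna_id[k], df$boxC_start[k], df$boxD_start[k],
                   df$boxDprime_start[k], df$boxCprime_start[k])
  })
  names(out) <- df$snorna_id
  out
}

#' @rdname read_box_annotation
#' @param boxes named list of `box_annotation` objects.
#' @export
write_box_annotation <- function(boxes, path) {
  df <- data.frame(
    snorna_id = vapply(boxes, function(b) b$snorna_id, character(1)),
    boxC_start = vapply(boxes, function(b) b$boxC[1], integer(1)),
    boxD_start = vapply(boxes, function(b) b$boxD[1], integer(1)),
    boxDprime_start = vapply(boxes, function(b) b$boxDprime[1], integer(1)),
    boxCprime_start = vapply(boxes, function(b) b$boxCprime[1], integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Guide geometry of a duplex relative to box D or D'
#'
#' For offsets k = 1..16 upstream of the chosen box, reports whether the
#' snoRNA position `box_start - k` is paired in the duplex, whether the
#' pair is exact (Watson-Crick; G-U is not exact), and the partner
#' position on the target transcript. The predicted methylation target is
#' the partner of offset 5 (the +5 rule). Offsets outside the snoRNA
#' fragment are unpaired.
#'
#' @param duplex a `duplex` over (snoRNA fragment, target fragment).
#' @param sno_frag `c(tx_begin, tx_end)` of the snoRNA fragment on the
#'   snoRNA reference entry (the coordinate system of `boxes`).
#' @param target_frag `c(tx_begin, tx_end)` of the target fragment.
#' @param boxes a `box_annotation` for the snoRNA entry.
#' @param box `"D"` or `"Dprime"`.
#' @param sno_side which duplex fragment is the snoRNA (1 or 2).
#' @param n_offsets number of upstream offsets examined.
#' @return object of class `guide_geometry`: list with `box`, `offsets`
#'   (data.frame k, sno_pos, paired, exact, target_pos), `box_exact`
#'   (logical(4): exact pairing of each box nucleotide), `n_pairs_total`,
#'   `predicted_target_pos` (target-transcript 1-based, `NA` if offset 5
#'   unpaired).
#' @export
guide_geometry <- function(duplex, sno_frag, target_frag, boxes,
                           box = c("D", "Dprime"), sno_side = 1L,
                           n_offsets = 16L) {
  box <- match.arg(box)
  bx <- if (box == "D") boxes$boxD else boxes$boxDprime
  if (anyNA(bx)) stop("box ", box, " not annotated")
  box_start <- bx[1]
  em <- exactness_mask(duplex)
  p <- duplex$pairs
  if (sno_side == 2L) {
    p <- cbind(i = p[, 2], j = p[, 1])  # per-pair exact flags are side-free
  }
  exact_pair <- em$exact

  lookup <- function(sno_pos) {
    # snoRNA tx position -> (paired, exact, target tx position)
    if (sno_pos < sno_frag[1] || sno_pos > sno_frag[2]) {
      return(c(paired = FALSE, exact = FALSE, target = NA_integer_))
    }
    loc <- sno_pos - sno_frag[1] + 1L
    hit <- which(p[, 1] == loc)
    if (!length(hit)) {
      return(c(paired = FALSE, exact = FALSE, target = NA_integer_))
    }
    c(paired = TRUE, exact = exact_pair[hit[1]],
      target = target_frag[1] + p[hit[1], 2] - 1L)
  }

  ks <- seq_len(n_offsets)
  rows <- t(vapply(box_start - ks, lookup, c(paired = 0, exact = 0, target = 0)))
  offsets <- data.frame(k = ks, sno_pos = box_start - ks,
                        paired = as.logical(rows[, "paired"]),
                        exact = as.logical(rows[, "exact"]),
                        target_pos = ifelse(rows[, "paired"] > 0,
                                            as.integer(rows[, "target"]),
                                            NA_integer_))
  box_rows <- t(vapply(box_start + 0:3, lookup,
                       c(paired = 0, exact = 0, target = 0)))
  predicted <- offsets$target_pos[offsets$k == 5L]
  structure(list(box = box, offsets = offsets,
                 box_exact = as.logical(box_rows[, "exact"]),
                 n_pairs_total = duplex$n_pairs,
                 predicted_target_pos = predicted),
            class = "guide_geometry")
}

#' @export
print.guide_geometry <- function(x, ...) {
  flag <- function(p, e) ifelse(e, "E", ifelse(p, "p", "."))
  cat("guide_geometry box", x$box, "-", x$n_pairs_total, "total pairs\n")
  cat(" offsets 1..16:",
      paste(flag(x$offsets$paired, x$offsets$exact), collapse = ""), "\n")
  cat(" box exact:", paste(ifelse(x$box_exact, "E", "."), collapse = ""),
      " predicted target:",
      ifelse(is.na(x$predicted_target_pos), "none", x$predicted_target_pos),
      "\n")
  invisible(x)
}
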