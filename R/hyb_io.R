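# Reader/writer for the hyb chimera dialect.
#
# One chimera per tab-delimited line, 15 mandatory fields:
#   read_id  read_seq  energy(or ".")
#   tx1  read1_begin  read1_end  tx1_begin  tx1_end  score1
#   tx2  read2_begin  read2_end  tx2_begin  tx2_end  score2
# All coordinates 1-based inclusive. Unknown trailing columns are
# preserved verbatim (hyb output variants differ) and re-emitted on write.

.HYB_COLS <- c("read_id", "read_seq", "energy",
               "tx1", "r1_begin", "r1_end", "t1_begin", "t1_end", "score1",
               "tx2", "r2_begin", "r2_end", "t2_begin", "t2_end", "score2")

#' Read a hyb-dialect chimera table
#'
#' Parses tab-delimited chimera records. Records violating the fragment
#' invariants (begin > end, coordinates < 1, fragments overlapping on the
#' read by more than `overlap_tol` nt) are rejected and reported, parsing
#' continues. Fragment order is normalised to read order (fragment 1 is
#' the one appearing first on the read).
#'
#' @param path path to the hyb file.
#' @param overlap_tol maximum tolerated overlap (nt) of the two fragments
#'   on the read.
#' @return a `data.frame` of class `hyb_chimeras` with columns
#'   `read_id, read_seq, energy` (numeric, `NA` for "."), the six fields
#'   of each fragment, and `extra` (verbatim trailing columns, `""` if
#'   none). Rejected lines are attached as `attr(x, "errors")`, a
#'   data.frame of (line, message).
#' @export
read_chimeras <- function(path, overlap_tol = 4L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  errs <- list()
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 15L) {
      errs[[length(errs) + 1L]] <- data.frame(
        line = k, message = sprintf("expected >= 15 fields, got %d", length(f)))
      next
    }
    num <- suppressWarnings(as.numeric(f[c(5:8, 11:14)]))
    if (anyNA(num)) {
      errs[[length(errs) + 1L]] <- data.frame(
        line = k, message = "non-numeric coordinate field")
      next
    }
    co <- as.integer(num)
    r1 <- co[1:2]; t1 <- co[3:4]; r2 <- co[5:6]; t2 <- co[7:8]
    msg <- NULL
    if (r1[1] > r1[2] || r2[1] > r2[2]) msg <- "read_end < read_begin"
    else if (t1[1] > t1[2] || t2[1] > t2[2]) msg <- "tx_end < tx_begin"
    else if (any(co < 1L)) msg <- "coordinate < 1"
    if (is.null(msg)) {
      # normalise to read order
      if (r2[1] < r1[1]) {
        tmp <- f[4:9]; f[4:9] <- f[10:15]; f[10:15] <- tmp
        tr <- r1; r1 <- r2; r2 <- tr
        tt <- t1; t1 <- t2; t2 <- tt
      }
      ov <- r1[2] - r2[1] + 1L
      if (ov > overlap_tol) msg <- sprintf("fragments overlap by %d nt on read", ov)
    }
    if (!is.null(msg)) {
      errs[[length(errs) + 1L]] <- data.frame(line = k, message = msg)
      next
    }
    energy <- if (f[3] == ".") NA_real_ else suppressWarnings(as.numeric(f[3]))
    rows[[k]] <- data.frame(
      read_id = f[1], read_seq = toupper(f[2]), energy = energy,
      tx1 = f[4], r1_begin = r1[1], r1_end = r1[2],
      t1_begin = t1[1], t1_end = t1[2], score1 = as.numeric(f[9]),
      tx2 = f[10], r2_begin = r2[1], r2_end = r2[2],
      t2_begin = t2[1], t2_end = t2[2], score2 = as.numeric(f[15]),
      extra = if (length(f) > 15L) paste(f[-(1:15)], collapse = "\t") else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), read_seq = character(0),
                      energy = numeric(0),
                      tx1 = character(0), r1_begin = integer(0),
                      r1_end = integer(0), t1_begin = integer(0),
                      t1_end = integer(0), score1 = numeric(0),
                      tx2 = character(0), r2_begin = integer(0),
                      r2_end = integer(0), t2_begin = integer(0),
                      t2_end = integer(0), score2 = numeric(0),
                      extra = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  err_df <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(0), message = character(0))
  attr(out, "errors") <- err_df
  class(out) <- c("hyb_chimeras", class(out))
  out
}

#' Write chimera records in the hyb dialect
#'
#' Inverse of [read_chimeras()]: writing then re-reading then re-writing
#' is a byte-identical fixpoint. Energies are serialised with two
#' decimals; missing energy as `"."`.
#'
#' @param records a chimera data.frame as returned by [read_chimeras()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chimeras <- function(records, path) {
  fmt_num <- function(x) {
    # integers without decimal point, otherwise shortest plain representation
    ifelse(x == round(x), sprintf("%d", as.integer(x)),
           sub("0+$", "", sprintf("%.6f", x)))
  }
  n <- nrow(records)
  if (n == 0L) { writeLines(character(0), path); return(invisible(path)) }
  lines <- paste(
    records$read_id, records$read_seq,
    ifelse(is.na(records$energy), ".", sprintf("%.2f", records$energy)),
    records$tx1, records$r1_begin, records$r1_end,
    records$t1_begin, records$t1_end, fmt_num(records$score1),
    records$tx2, records$r2_begin, records$r2_end,
    records$t2_begin, records$t2_end, fmt_num(records$score2),
    sep = "\t")
  has_extra <- nzchar(records$extra)
  lines[has_extra] <- paste(lines[has_extra], records$extra[has_extra],
                            sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# fragment sequences of a chimera row (RNA alphabet), from the read
.fragment_seqs <- function(rec) {
  list(frag1 = as_rna(substring(rec$read_seq, rec$r1_begin, rec$r1_end)),
       frag2 = as_rna(substring(rec$read_seq, rec$r2_begin, rec$r2_end)))
}
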