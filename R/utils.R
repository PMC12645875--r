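# Shared low-level helpers: RNA alphabet handling and interval arithmetic.
# All coordinates in this package are 1-based, inclusive on both ends.

#' Normalize a nucleotide string to uppercase RNA
#'
#' DNA `T` is converted to `U`; lowercase is uppercased. Characters outside
#' `A/C/G/U/N` raise an error naming the offenders.
#'
#' @param x character scalar (or vector) of nucleotide sequence(s).
#' @param allow_empty logical; if `FALSE`, empty sequences are an error.
#' @return character vector of the same length, RNA uppercase.
#' @export
as_rna <- function(x, allow_empty = TRUE) {
  x <- toupper(as.character(x))
  x <- gsub("T", "U", x, fixed = TRUE)
  if (!allow_empty && any(!nzchar(x))) {
    stop("empty sequence not allowed")
  }
  bad <- gsub("[ACGUN]", "", x)
  if (any(nzchar(bad))) {
    stop("non-ACGU(N) symbols in sequence: ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]), collapse = ", "))
  }
  x
}

#' Reverse complement of an RNA string
#' @param x RNA string (A/C/G/U/N).
#' @return reverse complement, RNA alphabet.
#' @export
revcomp_rna <- function(x) {
  x <- as_rna(x)
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "")[[1]])
    comp <- c(A = "U", U = "A", G = "C", C = "G", N = "N")
    paste(comp[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Pairing predicates. N (or any non-canonical symbol) never pairs.
.is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

.is_gu_pair <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

.can_pair <- function(a, b) .is_wc_pair(a, b) | .is_gu_pair(a, b)

#' Nearest-edge distance between an interval and a point
#'
#' Distance is 0 when the point lies inside the (1-based, closed) interval.
#'
#' @param start,end interval bounds, `start <= end`.
#' @param pos point position(s).
#' @return non-negative integer distance(s).
#' @export
interval_point_distance <- function(start, end, pos) {
  pmax(0L, start - pos, pos - end)
}

# substring by 1-based closed interval, vectorised over the interval
.subseq1 <- function(seq, start, end) substring(seq, start, end)

# split a string into a character vector of single bases
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
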