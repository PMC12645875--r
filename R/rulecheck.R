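# Independent, naive re-statement of the guide-calling rules.
#
# This checker is a literal transcription of the published decision
# criteria, written without reference to (and sharing no code with) the
# classifier in classifier.R. It exists so that the classifier can be
# validated against an implementation that cannot inherit its bugs, and
# so that the synthetic-data generator can verify planted truth labels
# without using the code under test.

#' Naive guide-rule checker (independent oracle)
#'
#' Evaluates the strict and weak methylation-guide criteria for one box
#' from raw pairing vectors, by direct re-reading of the rules:
#' \enumerate{
#'   \item the nucleotide 5 upstream of the box pairs exactly AND the
#'     hybrid contains 12 or more base pairs;
#'   \item one or more nucleotides 2-4 upstream pair exactly;
#'   \item there is not exact pairing over the whole box;
#'   \item either a stretch of 8 nucleotides between 1 and 14 upstream all
#'     pair exactly, or a stretch of 11 between 1 and 16 with at most one
#'     mismatch.
#' }
#' G-U pairs are never exact. The weak rule: strict fails but the
#' nucleotide 5 upstream of the box is paired (G-U allowed).
#'
#' @param exact16 logical(16): exact pairing at offsets 1..16 upstream.
#' @param paired16 logical(16): any pairing at offsets 1..16 upstream.
#' @param box_exact4 logical(4): exact pairing of the 4 box nucleotides.
#' @param n_total total number of base pairs in the hybrid duplex.
#' @return `"strict"`, `"weak"`, or `"none"`.
#' @export
naive_guide_call <- function(exact16, paired16, box_exact4, n_total) {
  stopifnot(length(exact16) == 16L, length(paired16) == 16L,
            length(box_exact4) == 4L)

  strict <- FALSE
  if (exact16[5] == TRUE && n_total >= 12) {
    one_in_2_4 <- FALSE
    for (k in c(2, 3, 4)) if (exact16[k]) one_in_2_4 <- TRUE
    if (one_in_2_4) {
      whole_box <- box_exact4[1] && box_exact4[2] && box_exact4[3] &&
        box_exact4[4]
      if (!whole_box) {
        stretch8 <- FALSE
        for (s in 1:7) {           # windows of 8 inside 1..14
          all_ex <- TRUE
          for (k in s:(s + 7)) if (!exact16[k]) all_ex <- FALSE
          if (all_ex) stretch8 <- TRUE
        }
        stretch11 <- FALSE
        for (s in 1:6) {           # windows of 11 inside 1..16
          mism <- 0
          for (k in s:(s + 10)) if (!exact16[k]) mism <- mism + 1
          if (mism <= 1) stretch11 <- TRUE
        }
        if (stretch8 || stretch11) strict <- TRUE
      }
    }
  }
  if (strict) return("strict")
  if (paired16[5]) return("weak")
  "none"
}

#' Naive two-box guide call
#'
#' Applies [naive_guide_call()] to box D then box D' with the published
#' precedence: strict on either box wins over weak on either box.
#'
#' @param geomD,geomDprime lists with elements `exact16`, `paired16`,
#'   `box_exact4`, `n_total` (either may be `NULL` if the box is absent).
#' @return `"strict"`, `"weak"`, or `"none"`.
#' @export
naive_guide_call2 <- function(geomD, geomDprime = NULL) {
  res <- c()
  if (!is.null(geomD)) {
    res <- c(res, naive_guide_call(geomD$exact16, geomD$paired16,
                                   geomD$box_exact4, geomD$n_total))
  }
  if (!is.null(geomDprime)) {
    res <- c(res, naive_guide_call(geomDprime$exact16, geomDprime$paired16,
                                   geomDprime$box_exact4, geomDprime$n_total))
  }
  if ("strict" %in% res) return("strict")
  if ("weak" %in% res) return("weak")
  "none"
}
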