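# Intermolecular duplex prediction between the two fragments of a chimera.
#
# The default scoring model is a deliberately simple nearest-neighbour
# stacking model: only intermolecular, non-crossing pairs are allowed
# (pairs strictly increasing on fragment 1 and strictly decreasing on
# fragment 2, i.e. an antiparallel helix interrupted by bulges/interior
# loops). Energy (kcal/mol) is
#
#     dG = init + sum over contiguous pair steps of -(s(p) + s(q))
#              + sum over interior loops of (loop_open + loop_per_nt * L)
#
# with per-pair strengths s(GC), s(AU), s(GU) and L the total number of
# unpaired nucleotides in the loop. Loops wider than `max_gap` unpaired
# nucleotides on either side are disallowed (two helices further apart
# than that are treated as separate interactions). All arithmetic is done
# in integer tenths of a kcal/mol so scores compare exactly.

# internal unit scale: tenths of kcal/mol
.DUPLEX_UNIT <- 10L

#' Parameters for the internal duplex scoring model
#'
#' @param init helix initiation penalty, kcal/mol (applied once if the
#'   duplex has at least one pair).
#' @param loop_open penalty for opening a bulge/interior loop, kcal/mol.
#' @param loop_per_nt penalty per unpaired loop nucleotide, kcal/mol.
#' @param max_gap maximum unpaired nucleotides allowed on either side of a
#'   single interior loop.
#' @param pair_strength named numeric vector of per-pair stacking strengths
#'   (kcal/mol) for Watson-Crick GC and AU pairs and the GU wobble; a
#'   contiguous step between pairs p and q contributes `-(s(p)+s(q))`.
#' @param max_len maximum fragment length accepted by [predict_duplex()].
#' @param backend `"internal"` for the built-in dynamic program, or a
#'   function `(seq1, seq2, params) -> duplex` to substitute an external
#'   thermodynamic engine; downstream code only consumes the `duplex`
#'   contract, so backends are interchangeable.
#' @return a list of class `duplex_params`.
#' @export
duplex_params <- function(init = 3.0, loop_open = 1.0, loop_per_nt = 0.5,
                          max_gap = 10L,
                          pair_strength = c(GC = 1.6, AU = 0.9, GU = 0.5),
                          max_len = 200L, backend = "internal") {
  stopifnot(init >= 0, loop_open >= 0, loop_per_nt >= 0, max_gap >= 1,
            all(c("GC", "AU", "GU") %in% names(pair_strength)))
  structure(list(init = init, loop_open = loop_open,
                 loop_per_nt = loop_per_nt, max_gap = as.integer(max_gap),
                 pair_strength = pair_strength, max_len = as.integer(max_len),
                 backend = backend),
            class = "duplex_params")
}

#' Write / read duplex scoring parameters as a JSON config file
#' @param params a `duplex_params` object.
#' @param path file path.
#' @return `read_duplex_params` returns a `duplex_params` object.
#' @export
write_duplex_params <- function(params, path) {
  stopifnot(inherits(params, "duplex_params"))
  x <- params[setdiff(names(params), "backend")]
  x$pair_strength <- as.list(x$pair_strength)   # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_duplex_params
#' @export
read_duplex_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  duplex_params(init = x$init, loop_open = x$loop_open,
                loop_per_nt = x$loop_per_nt, max_gap = x$max_gap,
                pair_strength = unlist(x$pair_strength), max_len = x$max_len)
}

# integer-unit views of the parameter table
.units <- function(params) {
  list(init = as.integer(round(params$init * .DUPLEX_UNIT)),
       loop_open = as.integer(round(params$loop_open * .DUPLEX_UNIT)),
       loop_per_nt = as.integer(round(params$loop_per_nt * .DUPLEX_UNIT)),
       s = vapply(params$pair_strength[c("GC", "AU", "GU")],
                  function(v) as.integer(round(v * .DUPLEX_UNIT)), integer(1)))
}

# strength matrix in integer units; NA where the bases cannot pair
.strength_matrix <- function(ch1, ch2, u) {
  n <- length(ch1); m <- length(ch2)
  a <- matrix(ch1, n, m)
  b <- matrix(ch2, n, m, byrow = TRUE)
  sp <- matrix(NA_integer_, n, m)
  gc <- (a == "G" & b == "C") | (a == "C" & b == "G")
  au <- (a == "A" & b == "U") | (a == "U" & b == "A")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  sp[gc] <- u$s[["GC"]]; sp[au] <- u$s[["AU"]]; sp[gu] <- u$s[["GU"]]
  sp
}

.new_duplex <- function(pairs, score_units, seq1, seq2, params) {
  n <- nchar(seq1); m <- nchar(seq2)
  np <- nrow(pairs)
  s1 <- rep(".", n); s2 <- rep(".", m)
  if (np > 0) { s1[pairs[, 1]] <- "("; s2[pairs[, 2]] <- ")" }
  structure(list(
    pairs = pairs,
    n_pairs = np,
    dG = -score_units / .DUPLEX_UNIT,
    structure = paste0(paste(s1, collapse = ""), "&", paste(s2, collapse = "")),
    seq1 = seq1, seq2 = seq2, params = params), class = "duplex")
}

#' Predict the optimal intermolecular duplex between two RNA fragments
#'
#' Finds the maximum-scoring set of non-crossing intermolecular base pairs
#' (Watson-Crick or G-U wobble; `N` never pairs) between `seq1` and `seq2`
#' under the scoring model in `params`. Deterministic: ties are broken
#' toward more pairs, then toward 5'-most pairing on fragment 1.
#'
#' @param seq1,seq2 RNA (or DNA; `T` is converted) fragment sequences.
#' @param params a [duplex_params()] object; if its `backend` element is a
#'   function it is called instead of the internal dynamic program.
#' @return an object of class `duplex`: list with `pairs` (two-column
#'   integer matrix of 1-based positions `i` on `seq1`, `j` on `seq2`,
#'   increasing in `i`, decreasing in `j`), `n_pairs`, `dG` (kcal/mol),
#'   `structure` (dot-bracket over `"frag1&frag2"`), the input sequences
#'   and the parameters.
#' @export
predict_duplex <- function(seq1, seq2, params = duplex_params()) {
  seq1 <- as_rna(seq1, allow_empty = FALSE)
  seq2 <- as_rna(seq2, allow_empty = FALSE)
  if (is.function(params$backend)) {
    return(params$backend(seq1, seq2, params))
  }
  n <- nchar(seq1); m <- nchar(seq2)
  if (n > params$max_len || m > params$max_len) {
    stop("fragment longer than max_len (", params$max_len, ")")
  }
  uu <- .units(params)
  ch1 <- .chars(seq1); ch2 <- .chars(seq2)
  sp <- .strength_matrix(ch1, ch2, uu)

  M <- matrix(NA_real_, n, m)   # best score (units) with last pair at (i,j)
  NP <- matrix(0L, n, m)        # pair count of that solution
  BI <- matrix(NA_integer_, n, m); BJ <- matrix(NA_integer_, n, m)
  mg <- params$max_gap

  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (is.na(sp[i, j])) next
      # start a new duplex with (i,j) as its only pair
      best_score <- -uu$init; best_np <- 1L
      best_bi <- NA_integer_; best_bj <- NA_integer_
      ri <- seq.int(max(1L, i - 1L - mg), i - 1L)
      cj <- seq.int(j + 1L, min(m, j + 1L + mg))
      if (i > 1L && j < m) {
        sub <- M[ri, cj, drop = FALSE]
        if (any(!is.na(sub))) {
          a <- i - ri - 1L                       # unpaired on seq1
          b <- cj - j - 1L                       # unpaired on seq2
          gain <- -(uu$loop_open + uu$loop_per_nt * outer(a, b, "+"))
          # contiguous stack replaces the loop penalty
          if (a[length(a)] == 0L && b[1L] == 0L) {
            gain[length(a), 1L] <- sp[i - 1L, j + 1L] + sp[i, j]
          }
          cand <- sub + gain
          ok <- which(!is.na(cand))
          if (length(ok)) {
            npc <- NP[ri, cj, drop = FALSE]
            # lexicographic (score, npairs, 5'-most pred i, largest pred j)
            key <- ((cand[ok] * 256 + (npc[ok] + 1L)) * 256 +
                      (201 - ri[(ok - 1L) %% length(ri) + 1L])) * 256 +
                   cj[(ok - 1L) %/% length(ri) + 1L]
            w <- ok[which.max(key)]
            w_r <- (w - 1L) %% length(ri) + 1L
            w_c <- (w - 1L) %/% length(ri) + 1L
            sc <- cand[w]; npp <- NP[ri[w_r], cj[w_c]] + 1L
            if (sc > best_score || (sc == best_score && npp > best_np)) {
              best_score <- sc; best_np <- npp
              best_bi <- ri[w_r]; best_bj <- cj[w_c]
            }
          }
        }
      }
      M[i, j] <- best_score; NP[i, j] <- best_np
      BI[i, j] <- best_bi; BJ[i, j] <- best_bj
    }
  }

  # global optimum: empty duplex (score 0) vs best cell
  done <- which(!is.na(M))
  if (!length(done)) {
    return(.new_duplex(matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("i", "j"))),
                       0L, seq1, seq2, params))
  }
  ii <- (done - 1L) %% n + 1L
  jj <- (done - 1L) %/% n + 1L
  key <- ((M[done] * 256 + NP[done]) * 256 + (201 - ii)) * 256 + jj
  w <- which.max(key)
  if (M[done[w]] < 0 || (M[done[w]] == 0 && NP[done[w]] == 0L)) {
    return(.new_duplex(matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("i", "j"))),
                       0L, seq1, seq2, params))
  }
  # traceback
  pi <- ii[w]; pj <- jj[w]
  pr <- integer(0); pc <- integer(0)
  while (!is.na(pi)) {
    pr <- c(pi, pr); pc <- c(pj, pc)
    npi <- BI[pi, pj]; npj <- BJ[pi, pj]
    pi <- npi; pj <- npj
  }
  pairs <- cbind(i = pr, j = pc)
  .new_duplex(pairs, M[done[w]], seq1, seq2, params)
}

#' Score an explicit pair list under the duplex model
#'
#' Standalone evaluator used both for reporting and as the common scoring
#' table for [brute_force_duplex()]. Pairs must be non-crossing
#' (increasing `i`, decreasing `j`) and chemically valid; an interior loop
#' wider than `params$max_gap` on either side makes the structure
#' infeasible under the model and returns `Inf`.
#'
#' @param pairs two-column matrix of (i, j) 1-based pair positions.
#' @param seq1,seq2 the fragment sequences.
#' @param params a [duplex_params()] object.
#' @return energy in kcal/mol (`0` for an empty pair list, `Inf` if
#'   infeasible).
#' @export
duplex_energy <- function(pairs, seq1, seq2, params = duplex_params()) {
  seq1 <- as_rna(seq1); seq2 <- as_rna(seq2)
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2)
  np <- nrow(pairs)
  if (np == 0L) return(0)
  o <- order(pairs[, 1])
  pairs <- pairs[o, , drop = FALSE]
  if (np > 1 && (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) >= 0))) {
    stop("pairs must be strictly increasing in i and decreasing in j")
  }
  ch1 <- .chars(seq1); ch2 <- .chars(seq2)
  a <- ch1[pairs[, 1]]; b <- ch2[pairs[, 2]]
  if (!all(.can_pair(a, b))) {
    stop("pair citing non-complementary bases (corrupt duplex)")
  }
  uu <- .units(params)
  s <- ifelse(.is_wc_pair(a, b) & (a == "G" | a == "C"), uu$s[["GC"]],
              ifelse(.is_wc_pair(a, b), uu$s[["AU"]], uu$s[["GU"]]))
  e <- uu$init
  if (np > 1) {
    for (k in 2:np) {
      ga <- pairs[k, 1] - pairs[k - 1, 1] - 1L
      gb <- pairs[k - 1, 2] - pairs[k, 2] - 1L
      if (ga > params$max_gap || gb > params$max_gap) return(Inf)
      if (ga == 0L && gb == 0L) {
        e <- e - (s[k - 1] + s[k])
      } else {
        e <- e + uu$loop_open + uu$loop_per_nt * (ga + gb)
      }
    }
  }
  e / .DUPLEX_UNIT
}

#' Exhaustive-search duplex oracle
#'
#' Enumerates every non-crossing intermolecular pairing of the two
#' sequences and returns the best under the same parameter table as
#' [predict_duplex()] (ties: more pairs, then enumeration order, which
#' prefers 5'-most pairing on fragment 1). Intended as an independent
#' test oracle; the search shares no code with the dynamic program.
#'
#' @inheritParams predict_duplex
#' @return a `duplex` object.
#' @export
brute_force_duplex <- function(seq1, seq2, params = duplex_params()) {
  seq1 <- as_rna(seq1, allow_empty = FALSE)
  seq2 <- as_rna(seq2, allow_empty = FALSE)
  n <- nchar(seq1); m <- nchar(seq2)
  if (n + m > 24) stop("brute_force_duplex limited to len(seq1)+len(seq2) <= 24")
  ch1 <- .chars(seq1); ch2 <- .chars(seq2)
  can <- outer(ch1, ch2, .can_pair)

  env <- new.env(parent = emptyenv())
  env$best_e <- 0; env$best_np <- 0L
  env$best_pairs <- matrix(integer(0), 0, 2)
  cur_i <- integer(n); cur_j <- integer(n)

  consider <- function(k) {
    if (k == 0L) return(invisible())
    p <- cbind(cur_i[seq_len(k)], cur_j[seq_len(k)])
    e <- duplex_energy(p, seq1, seq2, params)
    if (is.infinite(e)) return(invisible())
    if (e < env$best_e - 1e-9 ||
        (abs(e - env$best_e) < 1e-9 && k > env$best_np)) {
      env$best_e <- e; env$best_np <- k; env$best_pairs <- p
    }
    invisible()
  }

  rec <- function(i, jmax, k) {
    if (i > n || jmax < 1L) { consider(k); return(invisible()) }
    # option: leave position i unpaired
    rec(i + 1L, jmax, k)
    # option: pair i with each available j (descending keeps non-crossing)
    for (j in seq.int(jmax, 1L)) {
      if (can[i, j]) {
        cur_i[k + 1L] <<- i; cur_j[k + 1L] <<- j
        rec(i + 1L, j - 1L, k + 1L)
      }
    }
    invisible()
  }
  rec(1L, m, 0L)

  pairs <- env$best_pairs
  colnames(pairs) <- c("i", "j")
  score_units <- as.integer(round(-env$best_e * .DUPLEX_UNIT))
  .new_duplex(pairs, score_units, seq1, seq2, params)
}

#' Exact-pairing mask of a duplex
#'
#' A pair is "exact" iff it is Watson-Crick (A-U or G-C); G-U wobble pairs
#' are paired but not exact. Returns per-pair flags and per-position
#' exact-pairing maps for both fragments.
#'
#' @param duplex a `duplex` object.
#' @param seq1,seq2 fragment sequences (default: those stored in `duplex`).
#' @return list with `exact` (logical per pair), `paired1`/`paired2` and
#'   `exact1`/`exact2` (logical per position of each fragment).
#' @export
exactness_mask <- function(duplex, seq1 = duplex$seq1, seq2 = duplex$seq2) {
  seq1 <- as_rna(seq1); seq2 <- as_rna(seq2)
  ch1 <- .chars(seq1); ch2 <- .chars(seq2)
  p <- duplex$pairs
  a <- ch1[p[, 1]]; b <- ch2[p[, 2]]
  if (nrow(p) && !all(.can_pair(a, b))) {
    stop("pair citing non-complementary bases (corrupt duplex)")
  }
  exact <- .is_wc_pair(a, b)
  paired1 <- logical(nchar(seq1)); paired2 <- logical(nchar(seq2))
  exact1 <- logical(nchar(seq1)); exact2 <- logical(nchar(seq2))
  if (nrow(p)) {
    paired1[p[, 1]] <- TRUE; paired2[p[, 2]] <- TRUE
    exact1[p[exact, 1]] <- TRUE; exact2[p[exact, 2]] <- TRUE
  }
  list(exact = exact, paired1 = paired1, paired2 = paired2,
       exact1 = exact1, exact2 = exact2)
}

#' Stability filter on predicted duplex energy
#'
#' Keeps interactions whose predicted folding energy is at or below the
#' threshold (default -12 kcal/mol, inclusive).
#'
#' @param duplex a `duplex` object, or a numeric dG.
#' @param threshold maximum (most positive) allowed dG, kcal/mol.
#' @return logical.
#' @export
energy_filter <- function(duplex, threshold = -12.0) {
  dG <- if (inherits(duplex, "duplex")) duplex$dG else as.numeric(duplex)
  dG <= threshold
}

#' @export
print.duplex <- function(x, ...) {
  cat("Intermolecular duplex:", x$n_pairs, "pairs, dG =",
      sprintf("%.1f", x$dG), "kcal/mol\n")
  cat(" ", x$structure, "\n")
  cat(" ", x$seq1, "&", x$seq2, "\n")
  invisible(x)
}
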