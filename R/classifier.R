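# The decision tree assigning each reproducible snoRNA-target interaction
# to one of: methylation_strict, methylation_weak, known_site_overlap,
# ancillary, blocking, structural, unclassified.

.CALL_LABELS <- c("methylation_strict", "methylation_weak",
                  "known_site_overlap", "ancillary", "blocking",
                  "structural", "unclassified")

#' Classifier configuration
#'
#' Houses every numeric criterion of the decision tree, with the published
#' defaults.
#'
#' @param min_total_pairs minimum base pairs in the hybrid duplex (G-U
#'   counted) for the strict rule.
#' @param guide_offset the +N rule offset (5: the methylated nucleotide
#'   pairs with the snoRNA position 5 upstream of box D/D').
#' @param seed_window offsets that must contain at least one exact pair
#'   (2-4 upstream).
#' @param stretch8_len,stretch8_window exact-stretch rule: `stretch8_len`
#'   consecutive exact offsets entirely within `stretch8_window`.
#' @param stretch11_len,stretch11_window,stretch11_mm relaxed stretch rule:
#'   `stretch11_len` consecutive offsets within `stretch11_window` with at
#'   most `stretch11_mm` non-exact positions.
#' @param ancillary_flank maximum distance (nt) to a same-family known
#'   site for the ancillary call (non-overlapping).
#' @param blocking_min_wc_pairs minimum perfect Watson-Crick pairs for the
#'   blocking call.
#' @param blocking_flank half-window (nt) around a known site that must
#'   contain those Watson-Crick pairs.
#' @param neighbor_separation sites closer than this (nt) to a site guided
#'   by the same snoRNA are excluded from blocking calls.
#' @param energy_threshold duplex stability threshold, kcal/mol
#'   (inclusive).
#' @param min_support minimum independent reads for a reproducible
#'   cluster.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(min_total_pairs = 12L, guide_offset = 5L,
                              seed_window = c(2L, 4L),
                              stretch8_len = 8L, stretch8_window = c(1L, 14L),
                              stretch11_len = 11L,
                              stretch11_window = c(1L, 16L),
                              stretch11_mm = 1L,
                              ancillary_flank = 100L,
                              blocking_min_wc_pairs = 22L,
                              blocking_flank = 17L,
                              neighbor_separation = 20L,
                              energy_threshold = -12.0,
                              min_support = 2L) {
  stopifnot(min_total_pairs > 0, guide_offset > 0,
            seed_window[1] <= seed_window[2],
            stretch8_len <= diff(stretch8_window) + 1L,
            stretch11_len <= diff(stretch11_window) + 1L,
            ancillary_flank > 0, blocking_flank > 0)
  structure(list(min_total_pairs = as.integer(min_total_pairs),
                 guide_offset = as.integer(guide_offset),
                 seed_window = as.integer(seed_window),
                 stretch8_len = as.integer(stretch8_len),
                 stretch8_window = as.integer(stretch8_window),
                 stretch11_len = as.integer(stretch11_len),
                 stretch11_window = as.integer(stretch11_window),
                 stretch11_mm = as.integer(stretch11_mm),
                 ancillary_flank = as.integer(ancillary_flank),
                 blocking_min_wc_pairs = as.integer(blocking_min_wc_pairs),
                 blocking_flank = as.integer(blocking_flank),
                 neighbor_separation = as.integer(neighbor_separation),
                 energy_threshold = as.numeric(energy_threshold),
                 min_support = as.integer(min_support)),
            class = "classifier_config")
}

#' Serialize / load a classifier configuration (JSON)
#' @param cfg a `classifier_config`.
#' @param path file path.
#' @export
write_classifier_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier_config
#' @export
read_classifier_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(classifier_config, x)
}

# does any run of `len` consecutive offsets inside window [w1,w2] have at
# most `mm` non-exact positions?
.has_stretch <- function(exact, len, window, mm) {
  lo <- window[1]; hi <- window[2]
  if (hi - lo + 1L < len) return(FALSE)
  for (s in lo:(hi - len + 1L)) {
    if (sum(!exact[s:(s + len - 1L)]) <= mm) return(TRUE)
  }
  FALSE
}

#' Strict methylation-guide criterion
#'
#' All four clauses must hold: (1) the offset-5 nucleotide pairs exactly
#' and the duplex has at least `min_total_pairs` pairs; (2) at least one
#' exact pair among offsets 2-4; (3) the four box nucleotides are not all
#' exactly paired; (4) a stretch of 8 consecutive exact offsets within
#' 1..14, or of 11 consecutive offsets within 1..16 with at most one
#' non-exact position. G-U pairs are never exact.
#'
#' @param geometry a [guide_geometry()] object.
#' @param cfg a [classifier_config()].
#' @return list `ok` (logical) and `evidence` (named logical per clause).
#' @export
check_strict <- function(geometry, cfg = classifier_config()) {
  ex <- geometry$offsets$exact
  ev <- c(
    offset5_exact = isTRUE(ex[cfg$guide_offset]),
    min_total_pairs = geometry$n_pairs_total >= cfg$min_total_pairs,
    seed_2_4_exact = any(ex[cfg$seed_window[1]:cfg$seed_window[2]]),
    box_not_fully_exact = !all(geometry$box_exact),
    stretch = .has_stretch(ex, cfg$stretch8_len, cfg$stretch8_window, 0L) ||
      .has_stretch(ex, cfg$stretch11_len, cfg$stretch11_window,
                   cfg$stretch11_mm))
  list(ok = all(ev), evidence = ev)
}

#' Weak methylation-guide criterion
#'
#' Consulted only when strict fails for both boxes: the offset-5
#' nucleotide pairs with the target, G-U allowed.
#'
#' @inheritParams check_strict
#' @return logical.
#' @export
check_weak <- function(geometry, cfg = classifier_config()) {
  isTRUE(geometry$offsets$paired[cfg$guide_offset])
}

#' Ancillary criterion
#'
#' True iff a known site guided by the same snoRNA family exists on the
#' target with nearest-edge distance in (0, `ancillary_flank`]; an
#' interval overlapping the site (distance 0) is not ancillary.
#'
#' @param target_interval `c(start, end)` of the target fragment span.
#' @param target_id target transcript id.
#' @param family snoRNA family of the interaction.
#' @param known_sites known-site data.frame.
#' @param cfg a [classifier_config()].
#' @return list `ok` and `site` (position of the supporting site or `NA`).
#' @export
check_ancillary <- function(target_interval, target_id, family, known_sites,
                            cfg = classifier_config()) {
  s <- known_sites[known_sites$target_id == target_id &
                     known_sites$guide_family == family, , drop = FALSE]
  if (!nrow(s)) return(list(ok = FALSE, site = NA_integer_))
  d <- interval_point_distance(target_interval[1], target_interval[2],
                               s$position)
  hit <- which(d > 0 & d <= cfg$ancillary_flank)
  if (!length(hit)) return(list(ok = FALSE, site = NA_integer_))
  list(ok = TRUE, site = s$position[hit[which.min(d[hit])]])
}

#' Blocking criterion
#'
#' True iff some known site on the target has at least
#' `blocking_min_wc_pairs` perfect Watson-Crick pairs of the duplex whose
#' target positions all lie within `blocking_flank` nt of the site, and no
#' site guided by this snoRNA's own family lies closer than
#' `neighbor_separation` nt to that site (a snoRNA guiding methylation at
#' a closely neighbouring site is not called blocking there).
#'
#' @param duplex a `duplex` (snoRNA fragment vs target fragment).
#' @param target_frag `c(tx_begin, tx_end)` of the target fragment.
#' @param target_id target transcript id.
#' @param family snoRNA family of the interaction.
#' @param known_sites known-site data.frame.
#' @param target_side which duplex side is the target (default 2).
#' @param cfg a [classifier_config()].
#' @return list `ok` and `site`.
#' @export
check_blocking <- function(duplex, target_frag, target_id, family,
                           known_sites, target_side = 2L,
                           cfg = classifier_config()) {
  s <- known_sites[known_sites$target_id == target_id, , drop = FALSE]
  if (!nrow(s) || duplex$n_pairs < cfg$blocking_min_wc_pairs) {
    return(list(ok = FALSE, site = NA_integer_))
  }
  em <- exactness_mask(duplex)
  tcol <- if (target_side == 2L) 2L else 1L
  wc_pos <- target_frag[1] + duplex$pairs[em$exact, tcol] - 1L
  own <- known_sites$position[known_sites$target_id == target_id &
                                known_sites$guide_family == family]
  for (k in seq_len(nrow(s))) {
    site <- s$position[k]
    n_wc <- sum(wc_pos >= site - cfg$blocking_flank &
                  wc_pos <= site + cfg$blocking_flank)
    if (n_wc < cfg$blocking_min_wc_pairs) next
    if (length(own) && any(abs(own - site) < cfg$neighbor_separation)) next
    return(list(ok = TRUE, site = site))
  }
  list(ok = FALSE, site = NA_integer_)
}

#' Classify one snoRNA-target interaction
#'
#' Applies the decision tree in fixed precedence: strict (box D, then box
#' D'; when both pass, the box whose predicted site matches a known
#' same-family site is reported, box D on ties) -> weak -> overlap with a
#' site guided by this snoRNA (known_site_overlap) -> ancillary ->
#' blocking -> structural (rRNA targets) / unclassified (other targets).
#' Weak calls never fall through to the ancillary/blocking/structural
#' buckets.
#'
#' @param duplex a `duplex` between the snoRNA fragment (side 1) and the
#'   target fragment (side 2).
#' @param sno_frag,target_frag fragment spans `c(tx_begin, tx_end)` on the
#'   snoRNA entry and the target transcript.
#' @param target_id target transcript id.
#' @param target_biotype target biotype (`"rRNA"` routes the terminal
#'   bucket to `structural`).
#' @param family snoRNA family.
#' @param boxes a `box_annotation` for the snoRNA entry, or `NULL`
#'   (-> `unclassified` with reason).
#' @param known_sites known-site data.frame.
#' @param cfg a [classifier_config()].
#' @return list of class `interaction_call`: `label`, `box_used`,
#'   `predicted_site` (target position or `NA`), `matched_known_site`,
#'   `supporting_site` (ancillary/blocking site), `reason`, and
#'   `evidence` (named logicals of every criterion evaluated).
#' @export
classify_interaction <- function(duplex, sno_frag, target_frag, target_id,
                                 target_biotype, family, boxes, known_sites,
                                 cfg = classifier_config()) {
  res <- function(label, box_used = NA_character_,
                  predicted_site = NA_integer_,
                  matched_known_site = NA_integer_,
                  supporting_site = NA_integer_, reason = NA_character_,
                  evidence = logical(0)) {
    structure(list(label = label, box_used = box_used,
                   predicted_site = predicted_site,
                   matched_known_site = matched_known_site,
                   supporting_site = supporting_site, reason = reason,
                   evidence = evidence),
              class = "interaction_call")
  }
  if (is.null(boxes) || anyNA(boxes$boxD)) {
    return(res("unclassified", reason = "missing box D annotation"))
  }
  geoms <- list()
  geoms$D <- guide_geometry(duplex, sno_frag, target_frag, boxes, "D")
  if (!anyNA(boxes$boxDprime)) {
    geoms$Dprime <- guide_geometry(duplex, sno_frag, target_frag, boxes,
                                   "Dprime")
  }

  strict <- lapply(geoms, check_strict, cfg = cfg)
  ok <- vapply(strict, function(x) x$ok, logical(1))
  evidence <- unlist(lapply(names(strict), function(b) {
    stats::setNames(strict[[b]]$evidence,
                    paste0("strict_", b, "_", names(strict[[b]]$evidence)))
  }))
  site_match <- function(b) {
    pos <- geoms[[b]]$predicted_target_pos
    if (is.na(pos)) return(NA_integer_)
    hit <- known_sites$position[known_sites$target_id == target_id &
                                  known_sites$guide_family == family &
                                  known_sites$position == pos]
    if (length(hit)) hit[1] else NA_integer_
  }
  if (any(ok)) {
    passing <- names(ok)[ok]
    matches <- vapply(passing, site_match, integer(1))
    use <- if (any(!is.na(matches))) passing[which(!is.na(matches))[1]]
           else passing[1]            # box D first in `geoms`, so D on ties
    return(res("methylation_strict",
               box_used = if (use == "D") "D" else "Dprime",
               predicted_site = geoms[[use]]$predicted_target_pos,
               matched_known_site = matches[[use]],
               evidence = evidence))
  }

  weak <- vapply(geoms, check_weak, logical(1), cfg = cfg)
  evidence <- c(evidence,
                stats::setNames(weak, paste0("weak_offset5_paired_",
                                             names(weak))))
  if (any(weak)) {
    use <- names(weak)[weak][1]
    pos <- geoms[[use]]$offsets$target_pos[cfg$guide_offset]
    return(res("methylation_weak",
               box_used = if (use == "D") "D" else "Dprime",
               predicted_site = pos, matched_known_site = site_match(use),
               evidence = evidence))
  }

  # overlap with a site this snoRNA is known to guide
  own <- known_sites[known_sites$target_id == target_id &
                       known_sites$guide_family == family, , drop = FALSE]
  overlap_own <- nrow(own) > 0 &&
    any(interval_point_distance(target_frag[1], target_frag[2],
                                own$position) == 0)
  evidence <- c(evidence, overlap_own_site = overlap_own)
  if (overlap_own) {
    hit <- own$position[interval_point_distance(target_frag[1],
                                                target_frag[2],
                                                own$position) == 0][1]
    return(res("known_site_overlap", matched_known_site = hit,
               evidence = evidence))
  }

  anc <- check_ancillary(target_frag, target_id, family, known_sites, cfg)
  evidence <- c(evidence, ancillary = anc$ok)
  if (anc$ok) {
    return(res("ancillary", supporting_site = anc$site, evidence = evidence))
  }

  blk <- check_blocking(duplex, target_frag, target_id, family, known_sites,
                        cfg = cfg)
  evidence <- c(evidence, blocking = blk$ok)
  if (blk$ok) {
    return(res("blocking", supporting_site = blk$site, evidence = evidence))
  }

  if (identical(target_biotype, "rRNA")) {
    res("structural", evidence = evidence)
  } else {
    res("unclassified", reason = "no criterion met (non-rRNA target)",
        evidence = evidence)
  }
}

#' @export
print.interaction_call <- function(x, ...) {
  cat("interaction_call:", x$label,
      if (!is.na(x$box_used)) paste0("(box ", x$box_used, ")") else "", "\n")
  if (!is.na(x$predicted_site)) cat(" predicted site:", x$predicted_site, "\n")
  if (!is.na(x$matched_known_site))
    cat(" matched known site:", x$matched_known_site, "\n")
  invisible(x)
}
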