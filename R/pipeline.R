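# End-to-end orchestration: parse -> intramolecular split -> duplex
# folding -> energy filter -> reproducibility clustering -> mismap filter
# -> classification -> feature annotation -> summaries. Deterministic for
# a fixed configuration; every stage writes a TSV and a counts line.

#' Pipeline configuration
#'
#' @param chimeras,gtf,fasta,sites input paths (hyb chimera table, GTF
#'   annotation, per-transcript unspliced FASTA, known-site TSV; `sites`
#'   may be `NULL`).
#' @param boxes optional curated box-annotation TSV; snoRNAs without a
#'   curated row fall back to [detect_boxes()] on the reference entry.
#' @param out_dir output directory (created; a copy of the configuration
#'   is written into it).
#' @param classifier a [classifier_config()].
#' @param duplex a [duplex_params()].
#' @param flank snoRNA reference-extension, nt.
#' @param min_overlap clustering fragment-overlap threshold, nt.
#' @param mismap_identity,mismap_cov mismap-filter thresholds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(chimeras, gtf, fasta, sites = NULL, boxes = NULL,
                            out_dir = tempfile("snoclash_run"),
                            classifier = classifier_config(),
                            duplex = duplex_params(), flank = 20L,
                            min_overlap = 1L, mismap_identity = 0.75,
                            mismap_cov = 0.7) {
  structure(list(chimeras = chimeras, gtf = gtf, fasta = fasta,
                 sites = sites, boxes = boxes, out_dir = out_dir,
                 classifier = classifier, duplex = duplex,
                 flank = as.integer(flank),
                 min_overlap = as.integer(min_overlap),
                 mismap_identity = mismap_identity, mismap_cov = mismap_cov),
            class = "pipeline_config")
}

# fold all records (memoised on the fragment-sequence pair); returns the
# records with the energy column filled
.fold_records <- function(records, params) {
  cache <- new.env(parent = emptyenv())
  dup <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    fr <- .fragment_seqs(records[i, ])
    key <- paste(fr$frag1, fr$frag2, sep = "&")
    d <- cache[[key]]
    if (is.null(d)) {
      d <- predict_duplex(fr$frag1, fr$frag2, params)
      cache[[key]] <- d
    }
    dup[[i]] <- d
    records$energy[i] <- d$dG
  }
  attr(records, "duplexes") <- dup
  records
}

# orient a record so the snoRNA is fragment 1; returns NULL if no side is
# a snoRNA
.orient_sno <- function(rec, annotation) {
  b1 <- .biotype_of(rec$tx1, annotation)
  b2 <- .biotype_of(rec$tx2, annotation)
  if (b1 == "snoRNA") {
    list(sno_id = rec$tx1, sno_frag = c(rec$t1_begin, rec$t1_end),
         target_id = rec$tx2, target_frag = c(rec$t2_begin, rec$t2_end),
         target_biotype = b2, swap = FALSE)
  } else if (b2 == "snoRNA") {
    list(sno_id = rec$tx2, sno_frag = c(rec$t2_begin, rec$t2_end),
         target_id = rec$tx1, target_frag = c(rec$t1_begin, rec$t1_end),
         target_biotype = b1, swap = TRUE)
  } else NULL
}

#' Classify reproducible clusters
#'
#' Runs the decision tree on each cluster, using the member record with
#' the best (lowest) predicted energy as the representative duplex.
#'
#' @param clusters an `interaction_clusters` data.frame.
#' @param records the folded chimera records the clusters were built from.
#' @param annotation an `annotation_set`.
#' @param boxes named list of `box_annotation` objects keyed by snoRNA
#'   reference-entry id.
#' @param cfg a [classifier_config()].
#' @param duplex_params a [duplex_params()].
#' @return data.frame of calls: cluster_id, label, box_used,
#'   predicted_site, matched_known_site, supporting_site, sno_id,
#'   target_id, reason, plus one logical column per evidence flag.
#' @export
classify_clusters <- function(clusters, records, annotation, boxes,
                              cfg = classifier_config(),
                              duplex_params = duplex_params()) {
  member_rows <- attr(clusters, "member_rows")
  if (nrow(clusters) == 0L) {
    return(data.frame(cluster_id = character(0), label = character(0),
                      box_used = character(0), predicted_site = integer(0),
                      matched_known_site = integer(0),
                      supporting_site = integer(0), sno_id = character(0),
                      target_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- vector("list", nrow(clusters))
  for (k in seq_len(nrow(clusters))) {
    ix <- member_rows[[clusters$cluster_id[k]]]
    rep_i <- ix[order(records$energy[ix], records$read_id[ix])][1]
    rec <- records[rep_i, ]
    ori <- .orient_sno(rec, annotation)
    if (is.null(ori)) {
      call <- list(label = "unclassified", box_used = NA, predicted_site = NA,
                   matched_known_site = NA, supporting_site = NA,
                   reason = "no snoRNA fragment", evidence = logical(0))
      ori <- list(sno_id = NA_character_, target_id = NA_character_)
    } else {
      fr <- .fragment_seqs(rec)
      seqs <- if (ori$swap) list(fr$frag2, fr$frag1) else list(fr$frag1,
                                                              fr$frag2)
      d <- predict_duplex(seqs[[1]], seqs[[2]], duplex_params)
      bx <- boxes[[ori$sno_id]]
      call <- classify_interaction(d, ori$sno_frag, ori$target_frag,
                                   ori$target_id, ori$target_biotype,
                                   family = ori$sno_id, boxes = bx,
                                   known_sites = annotation$known_sites,
                                   cfg = cfg)
    }
    ev <- call$evidence
    rows[[k]] <- cbind(
      data.frame(cluster_id = clusters$cluster_id[k], label = call$label,
                 box_used = if (is.null(call$box_used)) NA else call$box_used,
                 predicted_site = call$predicted_site,
                 matched_known_site = call$matched_known_site,
                 supporting_site = call$supporting_site,
                 sno_id = ori$sno_id, target_id = ori$target_id,
                 reason = call$reason, stringsAsFactors = FALSE),
      if (length(ev)) as.data.frame(as.list(ev)) else NULL)
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate classified clusters with target features
#'
#' For clusters whose target is an mRNA (or any multi-exon gene), assigns
#' the feature label, the host relation of the snoRNA, and branch-point
#' window membership of the overlapped intron.
#'
#' @param calls classification table ([classify_clusters()]).
#' @param clusters the cluster table.
#' @param annotation an `annotation_set`.
#' @return data.frame: cluster_id, feature, host_relation, intron_id,
#'   dist_to_3prime_ss, in_branchpoint_window.
#' @export
annotate_features <- function(calls, clusters, annotation) {
  rows <- vector("list", nrow(calls))
  for (k in seq_len(nrow(calls))) {
    cl <- clusters[clusters$cluster_id == calls$cluster_id[k], ]
    tid <- calls$target_id[k]
    tx <- if (!is.na(tid)) annotation$transcripts[[tid]] else NULL
    iv <- if (!is.na(tid) && !is.na(cl$tx1) && cl$tx1 == tid) {
      c(cl$t1_begin, cl$t1_end)
    } else c(cl$t2_begin, cl$t2_end)
    feature <- assign_feature(iv, tx)
    hrel <- if (!is.na(calls$sno_id[k]) && !is.null(tx)) {
      suppressWarnings(host_relation(calls$sno_id[k], tid, iv, annotation))
    } else "non_host"
    intron_id <- NA_character_; d3 <- NA_integer_; bp <- FALSE
    if (feature == "intron" && !is.null(tx) && nrow(tx$introns_local)) {
      ov <- pmin(iv[2], tx$introns_local[, 2]) -
        pmax(iv[1], tx$introns_local[, 1]) + 1L
      w <- which.max(ov)
      if (ov[w] > 0) {
        intr <- tx$introns_local[w, ]
        intron_id <- sprintf("%s.intron%d", tid, w)
        d3 <- max(0L, intr[2] - iv[2])
        bp <- branchpoint_window(iv, intr)
      }
    }
    rows[[k]] <- data.frame(cluster_id = calls$cluster_id[k],
                            feature = feature, host_relation = hrel,
                            intron_id = intron_id, dist_to_3prime_ss = d3,
                            in_branchpoint_window = bp,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full interaction-calling pipeline
#'
#' Executes all stages in order and writes per-stage TSVs, a summary, and
#' a MANIFEST with stage counts and record-conservation checks into
#' `config$out_dir`. Deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with all intermediate and final tables:
#'   `records`, `split`, `folded`, `energy_kept`, `clusters`,
#'   `mismap`, `calls`, `features`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    say(sprintf("[%s] %s", stage,
                paste(names(list(...)), unlist(list(...)), sep = "=",
                      collapse = " ")))
  }
  out <- function(name, df) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(classifier = unclass(config$classifier),
                            duplex = unclass(config$duplex)[
                              setdiff(names(config$duplex), "backend")],
                            flank = config$flank,
                            min_overlap = config$min_overlap,
                            mismap_identity = config$mismap_identity,
                            mismap_cov = config$mismap_cov),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  annotation <- read_annotation(config$gtf, config$fasta, config$sites)
  db <- build_reference_db(annotation, flank = config$flank)
  boxes <- list()
  if (!is.null(config$boxes)) boxes <- read_box_annotation(config$boxes)
  sno_ids <- db$meta$id[db$meta$biotype == "snoRNA"]
  for (sid in setdiff(sno_ids, names(boxes))) {
    boxes[[sid]] <- suppressWarnings(detect_boxes(db$sequences[[sid]], sid))
  }

  records <- read_chimeras(config$chimeras)
  note("parse", n = nrow(records), errors = nrow(attr(records, "errors")))
  if (nrow(records) == 0L) {
    say("empty chimera file: writing empty outputs")
  }

  split <- filter_intramolecular(records, annotation)
  note("intramolecular_split", inter = nrow(split$inter),
       intra = nrow(split$intra), quarantine = nrow(split$quarantine))
  out("intra.tsv", split$intra[, c("read_id", "tx1", "t1_begin", "t1_end",
                                   "t2_begin", "t2_end")])

  folded <- .fold_records(split$inter, config$duplex)
  keep <- energy_filter(folded$energy,
                        threshold = config$classifier$energy_threshold)
  keep[is.na(keep)] <- FALSE
  energy_kept <- folded[keep, , drop = FALSE]
  note("energy_filter", kept = nrow(energy_kept),
       removed = sum(!keep), threshold = config$classifier$energy_threshold)

  clusters_all <- cluster_reproducible(energy_kept,
                                       min_support = config$classifier$min_support,
                                       min_overlap = config$min_overlap)
  repro <- clusters_all[clusters_all$reproducible, , drop = FALSE]
  attr(repro, "member_rows") <-
    attr(clusters_all, "member_rows")[repro$cluster_id]
  note("reproducibility", clusters = nrow(clusters_all),
       reproducible = nrow(repro),
       dropped_reads = sum(clusters_all$support[!clusters_all$reproducible]))

  # mismap filter on the members of reproducible clusters, then re-cluster
  member_idx <- sort(unique(unlist(attr(repro, "member_rows"))))
  repro_records <- energy_kept[member_idx, , drop = FALSE]
  decoys <- db$sequences[db$meta$biotype == "rRNA" |
                           grepl("^U3", db$meta$id)]
  mm <- filter_mismap(repro_records, decoys, annotation,
                      min_identity = config$mismap_identity,
                      min_cov = config$mismap_cov)
  note("mismap_filter", kept = nrow(mm$kept), removed = nrow(mm$removed))
  out("filter_report.tsv", mm$report)
  clusters <- cluster_reproducible(mm$kept,
                                   min_support = config$classifier$min_support,
                                   min_overlap = config$min_overlap)
  final <- clusters[clusters$reproducible, , drop = FALSE]
  attr(final, "member_rows") <- attr(clusters, "member_rows")[final$cluster_id]
  out("clusters.tsv", as.data.frame(final))

  calls <- classify_clusters(final, mm$kept, annotation, boxes,
                             cfg = config$classifier,
                             duplex_params = config$duplex)
  note("classification", clusters = nrow(final),
       labels = paste(names(table(calls$label)), table(calls$label),
                      sep = ":", collapse = ","))
  out("calls.tsv", calls)

  features <- if (nrow(calls)) annotate_features(calls, final, annotation)
    else data.frame()
  out("features.tsv", features)

  pair_summary <- summarize_pair_types(final, annotation)
  out("summary.tsv", pair_summary)

  manifest$conservation <- list(
    parse = nrow(records),
    split_sum = nrow(split$inter) + nrow(split$intra) +
      nrow(split$quarantine),
    mismap_sum = nrow(mm$kept) + nrow(mm$removed),
    mismap_input = nrow(repro_records))
  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(annotation = annotation, db = db, boxes = boxes,
                 records = records, split = split, folded = folded,
                 energy_kept = energy_kept, clusters = final,
                 mismap = mm, calls = calls, features = features,
                 summary = pair_summary, manifest = manifest))
}

#' Score a pipeline run against synthetic ground truth
#'
#' Each planted interaction is scored by its expected disposition:
#' classified interactions must receive their truth label on a
#' reproducible cluster containing their reads; intramolecular stems must
#' be routed to the intramolecular set; mismap decoys must be removed by
#' the mismap filter; singletons must not appear in any reproducible
#' cluster.
#'
#' @param result a [run_pipeline()] result.
#' @param truth truth table from [generate_chimeras()].
#' @return list `accuracy` (fraction of interactions correct), `detail`
#'   (per-interaction data.frame).
#' @export
evaluate_against_truth <- function(result, truth) {
  per <- unique(truth[, c("interaction_id", "class", "expected_disposition")])
  read_cluster <- new.env(parent = emptyenv())
  member_rows <- attr(result$clusters, "member_rows")
  for (cid in names(member_rows)) {
    ids <- strsplit(result$clusters$members[
      result$clusters$cluster_id == cid], ",")[[1]]
    for (rid in ids) read_cluster[[rid]] <- cid
  }
  labels <- stats::setNames(result$calls$label, result$calls$cluster_id)
  ok <- logical(nrow(per)); got <- character(nrow(per))
  for (k in seq_len(nrow(per))) {
    rids <- truth$read_id[truth$interaction_id == per$interaction_id[k]]
    exp <- per$expected_disposition[k]
    cids <- unique(unlist(mget(rids, envir = read_cluster,
                               ifnotfound = list(NA_character_))))
    cids <- cids[!is.na(cids)]
    got[k] <- if (exp == "intramolecular") {
      if (all(rids %in% result$split$intra$read_id)) "intramolecular"
      else "not_intra"
    } else if (exp == "mismap_removed") {
      if (all(rids %in% result$mismap$removed$read_id)) "mismap_removed"
      else "not_removed"
    } else if (exp == "dropped_singleton") {
      if (length(cids) == 0L) "dropped_singleton" else "clustered"
    } else {
      if (length(cids) == 1L) unname(labels[cids]) else "unclustered"
    }
    ok[k] <- identical(got[k], exp)
  }
  list(accuracy = mean(ok),
       detail = data.frame(per, got = got, ok = ok,
                           stringsAsFactors = FALSE))
}
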