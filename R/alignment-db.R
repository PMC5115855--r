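# Stage 5: the alignment database.  Each stored record contributes one
# compact "baminfo" entry — derived positions, flags, library, summarized
# quality score and a virtual address, with all long strings (read name,
# CIGAR text, sequence, qualities, tags) deliberately omitted.  Entries are
# arranged in reference-position space under the clipped position, and
# additionally under the unclipped 5' position when an analyzer that needs
# it (duplicate marking) is registered.  Ordered traversal of the database
# yields the coordinate sort order, so no separate sorting step exists.
#
# Because baminfo carries no read names, mates are connected through a qname
# side table kept only during insertion and dropped by resolve_mates().

#' Build a baminfo database entry from an alignment record
#'
#' Summarizes the record into the compact fixed-size form the analyzer
#' plug-ins work on: clipped and unclipped positions, flag, mate info,
#' library id (resolved from the `RG` tag through the header's read groups;
#' an unknown read group warns and falls back to library 0), the
#' quality-sum score, and the record's virtual address.  When the record
#' carries an `MC` (mate CIGAR) tag, the mate's unclipped 5' position is
#' computed here; otherwise it is left unresolved for the pairing pass.
#'
#' @param rec A `bam_record`.
#' @param va The record's `virtual_address`.
#' @param header The `sam_header` (for read-group/library resolution).
#' @return A list of class `baminfo`.
#' @export
build_baminfo <- function(rec, va, header) {
  mapped <- bitwAnd(rec$flag, FLAG_UNMAPPED) == 0L && rec$ref_id >= 0L &&
    length(rec$cigar$op) > 0L
  u5 <- if (mapped) unclipped_5prime(rec) else NA_integer_
  uend <- if (mapped) unclipped_end(rec) else NA_integer_
  lib <- 0L
  rg <- get_tag(rec, "RG")
  if (!is.null(rg)) {
    hit <- match(rg$value, header$read_groups$id)
    if (is.na(hit)) {
      warning("unknown read group '", rg$value, "' (gsn ", rec$gsn,
              "); using default library")
    } else {
      lib <- header$read_groups$library_id[hit]
    }
  }
  mate_u5 <- NA_integer_
  mc <- get_tag(rec, "MC")
  mate_mapped <- bitwAnd(rec$flag, FLAG_PAIRED) != 0L &&
    bitwAnd(rec$flag, FLAG_MATE_UNMAPPED) == 0L && rec$mate_ref_id >= 0L
  if (!is.null(mc) && mate_mapped) {
    mate_u5 <- mate_unclipped_from_cigar(mc$value, rec$mate_pos,
                                         bitwAnd(rec$flag, FLAG_MATE_REVERSE) != 0L)
  }
  structure(list(
    ref_id = rec$ref_id,
    clipped_pos = rec$pos,
    unclipped_5prime = u5,
    alignment_end_unclipped = uend,
    flag = rec$flag,
    mate_ref_id = rec$mate_ref_id,
    mate_unclipped_5prime = mate_u5,
    library_id = lib,
    score = quality_score_sum(rec),
    va = va,
    gsn = rec$gsn,
    duplicate = FALSE,
    mate_gsn = NA_integer_,
    pair_score = NA_integer_
  ), class = "baminfo")
}

# Mate unclipped 5' from a CIGAR string (the MC tag), the mate's 0-based
# position and its strand.
mate_unclipped_from_cigar <- function(cigar_text, mate_pos, mate_reverse) {
  cg <- parse_cigar(cigar_text)
  clips <- clip_lengths(cg)
  if (!mate_reverse) {
    mate_pos - clips[["lead"]]
  } else {
    rlen <- sum(cg$len[cg$op %in% REF_OPS])
    mate_pos + rlen - 1L + clips[["trail"]]
  }
}

#' Create an alignment database
#'
#' @param with_unclipped Build the secondary arrangement keyed by the
#'   unclipped 5' position.  Required by (and requested through) analyzers
#'   such as duplicate marking; lookups on the unclipped arrangement error
#'   if it was not requested.
#' @return An environment of class `alignment_db`.
#' @export
alignment_db <- function(with_unclipped = FALSE) {
  db <- new.env(parent = emptyenv())
  db$infos <- vector("list", 1024L)
  db$n <- 0L
  db$with_unclipped <- with_unclipped
  db$clipped_index <- new.env(parent = emptyenv())
  db$unclipped_index <- if (with_unclipped) new.env(parent = emptyenv()) else NULL
  db$qname_table <- new.env(parent = emptyenv())  # side table, dropped after pairing
  db$mates_resolved <- FALSE
  db$segment_stamp <- 0L
  class(db) <- "alignment_db"
  db
}

pos_key <- function(ref_id, pos) paste0(ref_id, ":", pos)

#' Insert a baminfo entry into the database
#'
#' `qname` is used only to feed the transient mate-pairing side table (read
#' names are never stored in baminfo); pass it for paired primary records.
#'
#' @param db An [alignment_db()].
#' @param info A `baminfo`.
#' @param qname Optional read name for mate pairing.
#' @export
db_insert <- function(db, info, qname = NULL) {
  db$n <- db$n + 1L
  if (db$n > length(db$infos)) db$infos <- c(db$infos, vector("list", length(db$infos)))
  db$infos[[db$n]] <- info
  idx <- db$n
  if (info$ref_id >= 0L) {
    k <- pos_key(info$ref_id, info$clipped_pos)
    db$clipped_index[[k]] <- c(db$clipped_index[[k]], idx)
    if (db$with_unclipped && !is.na(info$unclipped_5prime)) {
      uk <- pos_key(info$ref_id, info$unclipped_5prime)
      db$unclipped_index[[uk]] <- c(db$unclipped_index[[uk]], idx)
    }
  }
  primary <- bitwAnd(info$flag, bitwOr(FLAG_SECONDARY, FLAG_SUPPLEMENTARY)) == 0L
  if (!is.null(qname) && primary && bitwAnd(info$flag, FLAG_PAIRED) != 0L) {
    db$qname_table[[qname]] <- c(db$qname_table[[qname]], idx)
  }
  invisible(NULL)
}

db_get <- function(db, idx) db$infos[[idx]]

#' Number of entries in the database
#' @param db An alignment database.
#' @export
db_count <- function(db) db$n

#' Look up baminfo entries by position
#'
#' `lookup_clipped()` gathers every entry whose (reference, clipped mapping
#' position) matches; `lookup_unclipped()` does the same on the unclipped
#' 5' arrangement and errors if that arrangement was not requested at
#' [alignment_db()] creation.  Entries come back in global-sequence-number
#' order.
#'
#' @param db An alignment database.
#' @param ref_id 0-based reference id.
#' @param pos 0-based position (clipped or unclipped 5', respectively).
#' @return List of `baminfo` entries (possibly empty).
#' @export
lookup_clipped <- function(db, ref_id, pos) {
  idx <- db$clipped_index[[pos_key(ref_id, pos)]]
  infos_in_gsn_order(db, idx)
}

#' @rdname lookup_clipped
#' @export
lookup_unclipped <- function(db, ref_id, pos) {
  if (!db$with_unclipped)
    stop("unclipped arrangement was not requested for this database")
  idx <- db$unclipped_index[[pos_key(ref_id, pos)]]
  infos_in_gsn_order(db, idx)
}

infos_in_gsn_order <- function(db, idx) {
  if (is.null(idx)) return(list())
  infos <- db$infos[idx]
  infos[order(vapply(infos, function(i) i$gsn, 0L))]
}

#' Resolve mate information through the qname side table
#'
#' Pairs the two primary ends of each paired template, filling in each
#' entry's mate global sequence number, the pair score (sum of both ends'
#' quality-sum scores), and — where the `MC` tag did not already provide it —
#' the mate's unclipped 5' position.  The side table is dropped afterwards.
#'
#' @param db An alignment database.
#' @return Invisibly, the number of pairs resolved.
#' @export
resolve_mates <- function(db) {
  n_pairs <- 0L
  for (qname in ls(db$qname_table)) {
    idx <- db$qname_table[[qname]]
    if (length(idx) != 2L) next   # mate missing from input: stays unpaired
    a <- db$infos[[idx[1]]]
    b <- db$infos[[idx[2]]]
    ps <- a$score + b$score
    a$pair_score <- ps; b$pair_score <- ps
    a$mate_gsn <- b$gsn; b$mate_gsn <- a$gsn
    if (is.na(a$mate_unclipped_5prime)) a$mate_unclipped_5prime <- b$unclipped_5prime
    if (is.na(b$mate_unclipped_5prime)) b$mate_unclipped_5prime <- a$unclipped_5prime
    db$infos[[idx[1]]] <- a
    db$infos[[idx[2]]] <- b
    n_pairs <- n_pairs + 1L
  }
  db$qname_table <- new.env(parent = emptyenv())
  db$mates_resolved <- TRUE
  invisible(n_pairs)
}

active_infos <- function(db) db$infos[seq_len(db$n)]

# Traversal order: (ref_id in header order, clipped position, gsn); entries
# with ref_id -1 (truly unmapped, no placement coordinate) come last in gsn
# order.  Unmapped records whose RNAME/POS carry the mate's coordinate sort
# there naturally, matching coordinate-sorted BAM convention.
traversal_order <- function(db) {
  infos <- active_infos(db)
  if (length(infos) == 0L) return(integer(0))
  ref <- vapply(infos, function(i) i$ref_id, 0L)
  pos <- vapply(infos, function(i) i$clipped_pos, 0L)
  gsn <- vapply(infos, function(i) i$gsn, 0L)
  order(ref < 0L, ref, pos, gsn)
}

#' Traverse the database in sort-key order
#'
#' Emits every entry in nondecreasing (reference id, clipped position,
#' global sequence number), truly unmapped entries last — the coordinate
#' sort order of the output BAM.  This is how the writer obtains sorted
#' output without a separate sorting step.
#'
#' @param db An alignment database.
#' @return List of `baminfo` entries.
#' @export
traverse_sorted <- function(db) {
  active_infos(db)[traversal_order(db)]
}

# --- segmentation of the unclipped-position space ---------------------------
#
# Analyzer parallelism decomposes the database into disjoint regions of the
# unclipped key space.  Each duplicate-candidate group has a single "owning
# key" — the (ref, unclipped 5') of the canonical first end for paired
# candidates, the record's own end otherwise — so any partition of owning
# keys keeps groups atomic and per-region analysis equals whole-database
# analysis.

owning_key_num <- function(info) {
  # linearized (ref, pos) owning coordinate; NA when ineligible
  k <- candidate_key(info)
  if (is.null(k)) return(NA_real_)
  k$owning
}

#' Partition the database into analyzer regions
#'
#' Splits the occupied unclipped-key space into `n_segments` disjoint
#' ranges that jointly cover every duplicate-candidate group; a group never
#' spans two ranges, which is what makes region-parallel analysis exactly
#' equal to whole-database analysis.
#'
#' @param db An alignment database (mates must be resolved).
#' @param n_segments Number of regions requested; fewer are returned when
#'   the occupied key space is smaller.
#' @return List of opaque region objects accepted by [mark_duplicates()].
#' @export
segment_regions <- function(db, n_segments = 1L) {
  stopifnot(n_segments >= 1L)
  keys <- vapply(active_infos(db), owning_key_num, 0)
  keys <- sort(unique(keys[!is.na(keys)]))
  db$segment_stamp <- db$segment_stamp + 1L
  if (length(keys) == 0L) {
    return(list(new_region(db, -Inf, Inf)))
  }
  n_segments <- min(n_segments, length(keys))
  cuts <- split(keys, ceiling(seq_along(keys) * n_segments / length(keys)))
  lapply(cuts, function(ks) new_region(db, min(ks), max(ks)))
}

new_region <- function(db, lo, hi) {
  structure(list(lo = lo, hi = hi, stamp = db$segment_stamp),
            class = "db_region")
}

region_contains <- function(region, key_num) {
  !is.na(key_num) & key_num >= region$lo & key_num <= region$hi
}
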