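# Plug-in framework.  Three kinds exist:
#   filter     — a pure predicate over alignment records, applied in the
#                streaming half of the pipeline; a chain of filters is the
#                conjunction of its predicates.
#   analyzer   — runs over the pooled alignment database after all input is
#                read, per segmented region; shipped: duplicate marking.
#   accelerator— a deflate-compatible compression backend the BAM writer can
#                route any subset of blocks to.
# Plug-ins are registered by name and attached at runtime via config/CLI.

plugin_registry <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  plugin_registry$filters <- list(region = make_region_filter)
  plugin_registry$analyzers <- list(dupmark = dupmark_analyzer())
  plugin_registry$backends <- list(
    zlib = zlib_backend,
    rdeflate = rdeflate_backend
  )
}

#' Register a plug-in
#'
#' `register_filter()` takes a factory `function(arg, header)` returning a
#' predicate over records; `register_analyzer()` an analyzer object (list
#' with `name`, `wants_unclipped_index`, and an `analyze(db, region)` hook);
#' `register_compression_backend()` a codec `function(payload, level)`
#' returning raw-deflate bytes (the same contract as zlib's raw deflate).
#'
#' @param name Plug-in name used on the CLI/config surface.
#' @param fn The factory, analyzer object, or codec function.
#' @export
register_filter <- function(name, fn) {
  plugin_registry$filters[[name]] <- fn
  invisible(NULL)
}

#' @rdname register_filter
#' @export
register_analyzer <- function(name, fn) {
  plugin_registry$analyzers[[name]] <- fn
  invisible(NULL)
}

#' @rdname register_filter
#' @export
register_compression_backend <- function(name, fn) {
  plugin_registry$backends[[name]] <- fn
  invisible(NULL)
}

lookup_plugin <- function(kind, name) {
  tbl <- plugin_registry[[kind]]
  if (is.null(tbl[[name]]))
    stop("unknown ", sub("s$", "", kind), " plug-in '", name,
         "'; available: ", paste(names(tbl), collapse = ", "))
  tbl[[name]]
}

# --- filters ----------------------------------------------------------------

#' Apply a filter chain to a record
#'
#' Filters are pure predicates; the chain keeps a record only if every
#' filter accepts it (drop as soon as any rejects), so the outcome is
#' invariant under filter reordering.
#'
#' @param rec A `bam_record`.
#' @param filters List of predicate functions.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
apply_filters <- function(rec, filters) {
  for (f in filters) if (!isTRUE(f(rec))) return(FALSE)
  TRUE
}

#' Region-overlap filter
#'
#' Keeps only records whose clipped alignment span overlaps the given
#' region, `"chr:start-end"` in the 1-based closed CLI dialect.  Unmapped
#' records never overlap and are dropped.
#'
#' @param arg Region string, e.g. `"chr1:1000-2000"`.
#' @param header The `sam_header` (resolves the reference name).
#' @return A predicate over `bam_record`s.
#' @export
make_region_filter <- function(arg, header) {
  m <- regmatches(arg, regexec("^([^:]+):([0-9]+)-([0-9]+)$", arg))[[1]]
  if (length(m) == 0L) stop("malformed region spec (want CHR:START-END): ", arg)
  ref <- ref_id_of(m[2], header)
  lo <- as.integer(m[3]) - 1L          # 0-based inclusive
  hi <- as.integer(m[4]) - 1L
  if (lo > hi) stop("region start exceeds end: ", arg)
  function(rec) {
    if (rec$ref_id != ref || rec$pos < 0L || length(rec$cigar$op) == 0L) return(FALSE)
    rec$pos <= hi && alignment_end(rec) >= lo
  }
}

# Build filter predicates from CLI-style specs like "region=chr1:100-200".
build_filters <- function(specs, header) {
  lapply(specs, function(spec) {
    parts <- strsplit(spec, "=", fixed = TRUE)[[1]]
    name <- parts[1]
    arg <- if (length(parts) > 1L) paste(parts[-1], collapse = "=") else ""
    factory <- lookup_plugin("filters", name)
    factory(arg, header)
  })
}

# --- duplicate marking ------------------------------------------------------

# Canonical duplicate-candidate key of a baminfo entry, or NULL when
# ineligible (secondary, supplementary, unmapped).  Paired candidates (both
# ends mapped) key on (library, end1, end2) with the two
# (ref, unclipped 5', strand) ends in lexicographic order, so the key is the
# same from whichever mate is seen; everything else keys on its own end
# alone, in a disjoint key space.  The "owning" linearized coordinate of the
# first end anchors the group to one analyzer region.
candidate_key <- function(info) {
  if (bitwAnd(info$flag, bitwOr(FLAG_SECONDARY, FLAG_SUPPLEMENTARY)) != 0L)
    return(NULL)
  if (bitwAnd(info$flag, FLAG_UNMAPPED) != 0L || info$ref_id < 0L ||
      is.na(info$unclipped_5prime))
    return(NULL)
  strand <- as.integer(bitwAnd(info$flag, FLAG_REVERSE) != 0L)
  paired <- bitwAnd(info$flag, FLAG_PAIRED) != 0L &&
    bitwAnd(info$flag, FLAG_MATE_UNMAPPED) == 0L &&
    info$mate_ref_id >= 0L && !is.na(info$mate_unclipped_5prime)
  lin <- function(ref, pos) ref * 2^33 + pos + 2^31
  if (paired) {
    mate_strand <- as.integer(bitwAnd(info$flag, FLAG_MATE_REVERSE) != 0L)
    e1 <- c(info$ref_id, info$unclipped_5prime, strand)
    e2 <- c(info$mate_ref_id, info$mate_unclipped_5prime, mate_strand)
    swap <- (e2[1] < e1[1]) || (e2[1] == e1[1] && (e2[2] < e1[2] ||
             (e2[2] == e1[2] && e2[3] < e1[3])))
    if (swap) { tmp <- e1; e1 <- e2; e2 <- tmp }
    list(
      paired = TRUE,
      key = paste("P", info$library_id, paste(e1, collapse = ","),
                  paste(e2, collapse = ","), sep = "|"),
      owning = lin(e1[1], e1[2])
    )
  } else {
    list(
      paired = FALSE,
      key = paste("U", info$library_id, info$ref_id, info$unclipped_5prime,
                  strand, sep = "|"),
      owning = lin(info$ref_id, info$unclipped_5prime)
    )
  }
}

#' Duplicate-candidate key of a baminfo entry
#'
#' @param info A `baminfo` (primary, mapped, with mates resolved).
#' @return A list with `paired`, `key` (canonical string) and `owning`
#'   (linearized region-anchor coordinate), or `NULL` when the entry is
#'   ineligible (secondary/supplementary/unmapped).
#' @export
duplicate_key <- function(info) candidate_key(info)

#' Mark duplicate alignments in the database
#'
#' Traverses the unclipped arrangement to gather duplicate candidates:
#' records (or pairs) whose unclipped 5' fragment coordinates and strands
#' coincide within a library.  In every group of two or more, the candidate
#' with the highest score — the summed quality-sum of both mates for pairs,
#' the record's own score otherwise — is kept as representative (ties go to
#' the lowest global sequence number) and all others have their duplicate
#' flag set; both mates of a duplicate pair are flagged.  Paired and
#' unpaired candidates live in disjoint key spaces and are never compared.
#'
#' @param db An [alignment_db()] with the unclipped arrangement, after
#'   [resolve_mates()].
#' @param region A region from [segment_regions()], or `NULL` for the whole
#'   database.
#' @return Number of records newly flagged.
#' @export
mark_duplicates <- function(db, region = NULL) {
  if (!db$with_unclipped)
    stop("duplicate marking requires the unclipped arrangement")
  if (!db$mates_resolved)
    stop("resolve_mates() must run before duplicate marking")
  if (!is.null(region)) {
    if (!inherits(region, "db_region") || region$stamp != db$segment_stamp)
      stop("region was not produced by the current segment_regions() call")
  }
  infos <- active_infos(db)
  keys <- lapply(infos, candidate_key)
  eligible <- !vapply(keys, is.null, TRUE)
  idx <- which(eligible)
  if (!is.null(region)) {
    owning <- vapply(keys[idx], function(k) k$owning, 0)
    idx <- idx[region_contains(region, owning)]
  }
  if (length(idx) == 0L) return(0L)
  key_str <- vapply(keys[idx], function(k) k$key, "")
  newly <- 0L
  for (grp in split(idx, key_str)) {
    newly <- newly + mark_group(db, grp)
  }
  newly
}

# Flag all non-representative members of one candidate group.  `grp` holds
# database indices sharing a key.  For paired keys each pair appears twice
# (once per mate); pairs are the competing units.
mark_group <- function(db, grp) {
  infos <- db$infos[grp]
  paired <- bitwAnd(infos[[1]]$flag, FLAG_PAIRED) != 0L &&
    !is.na(infos[[1]]$pair_score)
  newly <- 0L
  if (paired) {
    pair_id <- vapply(infos, function(i) min(i$gsn, i$mate_gsn), 0L)
    units <- split(seq_along(grp), pair_id)
    if (length(units) < 2L) return(0L)
    scores <- vapply(units, function(u) as.numeric(infos[[u[1]]]$pair_score), 0)
    min_gsn <- as.integer(names(units))
    best <- which(scores == max(scores))
    best <- best[which.min(min_gsn[best])]
    for (j in seq_along(units)) {
      if (j == best) next
      for (u in units[[j]]) {
        i <- grp[u]
        if (!db$infos[[i]]$duplicate) {
          db$infos[[i]]$duplicate <- TRUE
          newly <- newly + 1L
        }
      }
    }
  } else {
    if (length(grp) < 2L) return(0L)
    scores <- vapply(infos, function(i) as.numeric(i$score), 0)
    gsn <- vapply(infos, function(i) i$gsn, 0L)
    best <- which(scores == max(scores))
    best <- best[which.min(gsn[best])]
    for (j in seq_along(grp)) {
      if (j == best) next
      i <- grp[j]
      if (!db$infos[[i]]$duplicate) {
        db$infos[[i]]$duplicate <- TRUE
        newly <- newly + 1L
      }
    }
  }
  newly
}

dupmark_analyzer <- function() {
  list(
    name = "dupmark",
    wants_unclipped_index = TRUE,
    summarize = NULL,   # score/positions are already summarized into baminfo
    analyze = function(db, region) mark_duplicates(db, region)
  )
}

# --- compression backends ---------------------------------------------------

# Default codec: zlib raw deflate at the requested level.
zlib_backend <- function(payload, level = 6L) {
  .Call(C_deflate_raw, payload, as.integer(level))
}

# Alternate software codec built on R's own compressor: memCompress() emits
# a zlib stream (2-byte header, deflate data, Adler-32 trailer), so the raw
# deflate stream is recovered by stripping both.  The compression level is
# the compressor's default (not tunable here); used to exercise
# multi-backend routing.
rdeflate_backend <- function(payload, level = 6L) {
  z <- memCompress(payload, type = "gzip")
  if (length(z) < 6L || z[1] != as.raw(0x78))
    stop("unexpected stream framing from memCompress")
  z[3:(length(z) - 4L)]
}
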