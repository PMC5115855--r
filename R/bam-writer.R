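# Stage 7: BAM writing.  A single-threaded dispatcher walks the ordered
# stream of (virtual address, size) references and greedily packs them into
# block manifests of at most 64 KiB of uncompressed payload — using only
# addresses and sizes, never copying record bodies.  Block payloads are then
# materialized and deflate-compressed as independent units (in parallel when
# workers > 1), reassembled by block sequence number, and written in
# dispatch order, so output bytes are identical for any worker count.

#' Pack an ordered record stream into BAM block manifests
#'
#' Greedy single-pass packing: records are appended to the current manifest
#' while the summed encoded sizes stay within `max_payload`; a single record
#' larger than the cap gets a manifest of its own (and is split across BGZF
#' members at serialization).  Flattening the manifests reproduces the input
#' order exactly.
#'
#' @param sizes Integer vector of encoded record sizes, in stream order.
#' @param max_payload Uncompressed block payload cap in bytes.
#' @return List of integer index vectors into the input stream.
#' @export
dispatch_blocks <- function(sizes, max_payload = BGZF_MAX_PAYLOAD) {
  manifests <- list()
  current <- integer(0)
  acc <- 0
  for (i in seq_along(sizes)) {
    sz <- sizes[i]
    if (length(current) > 0L && acc + sz > max_payload) {
      manifests[[length(manifests) + 1L]] <- current
      current <- integer(0)
      acc <- 0
    }
    current <- c(current, i)
    acc <- acc + sz
    if (acc >= max_payload) {
      manifests[[length(manifests) + 1L]] <- current
      current <- integer(0)
      acc <- 0
    }
  }
  if (length(current) > 0L) manifests[[length(manifests) + 1L]] <- current
  manifests
}

# BAM header block: magic, header text, reference dictionary (the @SQ order
# defines the reference ids used in every record).
bam_header_bytes <- function(header) {
  text <- header$text
  refs <- header$sequences
  ref_bytes <- if (nrow(refs) > 0L) {
    do.call(c, lapply(seq_len(nrow(refs)), function(i) {
      nm <- charToRaw(refs$name[i])
      c(int32_le(length(nm) + 1L), nm, as.raw(0L), int32_le(refs$length[i]))
    }))
  } else raw(0)
  c(charToRaw("BAM"), as.raw(1L),
    int32_le(nchar(text, type = "bytes")), charToRaw(text),
    int32_le(nrow(refs)), ref_bytes)
}

# Set (or insert) SO:coordinate in the @HD line of the header text; used
# when the database drives the traversal and output is therefore sorted.
header_with_sort_order <- function(header, so = "coordinate") {
  text <- header$text
  if (grepl("^@HD\t", text)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
    hd <- lines[1]
    if (grepl("\tSO:[^\t]*", hd)) {
      hd <- sub("\tSO:[^\t]*", paste0("\tSO:", so), hd)
    } else {
      hd <- paste0(hd, "\tSO:", so)
    }
    lines[1] <- hd
    text <- paste0(paste(lines[lines != ""], collapse = "\n"), "\n")
  } else {
    text <- paste0("@HD\tVN:1.6\tSO:", so, "\n", text)
  }
  header$text <- text
  header
}

# Ordered map over block payloads; forks via parallel::mclapply when more
# than one worker is requested and the platform supports it.  Results are
# indexed by block number, so reassembly order never depends on completion
# order.
ordered_map <- function(xs, fn, workers = 1L) {
  if (workers > 1L && .Platform$OS.type == "unix" && length(xs) > 1L) {
    parallel::mclapply(xs, fn, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(xs, fn)
  }
}

#' Write a BGZF-compressed BAM file
#'
#' The source is either an alignment database (records are emitted in
#' [traverse_sorted()] order with the duplicate flag applied from baminfo at
#' serialization time, and the emitted header declares `SO:coordinate`) or a
#' direct ordered stream of virtual addresses (input order and header sort
#' order preserved) — exactly one of `db` and `stream` must be given.
#'
#' @param store The [record_store()] holding the record bodies.
#' @param header A `sam_header`.
#' @param path Output file path.
#' @param db An [alignment_db()] to drive sorted traversal, or `NULL`.
#' @param stream List of `virtual_address`es in stream order, or `NULL`.
#' @param workers Compression worker count.
#' @param level Deflate level (0-9).
#' @param backend Optional codec or list of codecs; with several codecs,
#'   blocks are routed round-robin across them (the accelerator-offload
#'   pattern); output decodes identically regardless of the routing split.
#' @return List with `path`, `n_records`, `n_blocks`.
#' @export
write_bam <- function(store, header, path, db = NULL, stream = NULL,
                      workers = 1L, level = 6L, backend = NULL) {
  if (is.null(db) == is.null(stream))
    stop("exactly one of db and stream must be supplied")
  sorted <- !is.null(db)
  if (sorted) {
    infos <- traverse_sorted(db)
    vas <- lapply(infos, function(i) i$va)
    dup <- vapply(infos, function(i) isTRUE(i$duplicate), TRUE)
    header <- header_with_sort_order(header)
  } else {
    vas <- stream
    dup <- logical(length(vas))
  }
  sizes <- vapply(vas, function(va) record_size(store, va), 0L)
  manifests <- dispatch_blocks(sizes)

  backends <- if (is.null(backend)) list(zlib_backend)
              else if (is.function(backend)) list(backend)
              else backend
  payload_of <- function(manifest) {
    parts <- lapply(manifest, function(i) {
      bytes <- fetch_bytes(store, vas[[i]])
      if (dup[i]) bytes <- patch_flag_duplicate(bytes)
      bytes
    })
    do.call(c, parts)
  }
  compress_one <- function(bi) {
    payload <- payload_of(manifests[[bi]])
    be <- backends[[(bi - 1L) %% length(backends) + 1L]]
    if (length(payload) <= BGZF_MAX_PAYLOAD) {
      bgzf_compress_block(payload, level, be)
    } else {
      # an oversized single record spans consecutive BGZF members
      chunks <- split(payload, (seq_along(payload) - 1L) %/% BGZF_MAX_PAYLOAD)
      do.call(c, lapply(chunks, bgzf_compress_block, level = level, backend = be))
    }
  }

  blocks <- ordered_map(seq_along(manifests), compress_one, workers = workers)

  con <- file(path, "wb")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok) unlink(path)   # abort leaves no partial file behind
  })
  hb <- bam_header_bytes(header)
  hchunks <- if (length(hb) > BGZF_MAX_PAYLOAD)
    split(hb, (seq_along(hb) - 1L) %/% BGZF_MAX_PAYLOAD) else list(hb)
  for (hc in hchunks)
    writeBin(bgzf_compress_block(hc, level, backends[[1]]), con)
  for (b in blocks) writeBin(b, con)
  writeBin(bgzf_eof(), con)
  ok <- TRUE
  list(path = path, n_records = length(vas), n_blocks = length(manifests))
}
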