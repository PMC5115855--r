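# BGZF framing.  A BGZF file is a series of gzip members, each carrying a
# "BC" extra field holding BSIZE (total member length - 1, <= 65535) and a
# raw-deflate stream of at most 64 KiB of uncompressed payload, followed by
# the standard CRC32/ISIZE gzip trailer; the file ends with a fixed 28-byte
# empty member (the EOF marker).

BGZF_MAX_PAYLOAD <- 65536L

# gzip member header with the 6-byte BC extra field; BSIZE patched in later.
bgzf_header_template <- function() {
  as.raw(c(0x1f, 0x8b, 0x08, 0x04,       # magic, CM=deflate, FLG=FEXTRA
           0x00, 0x00, 0x00, 0x00,       # MTIME
           0x00, 0xff,                   # XFL, OS=unknown
           0x06, 0x00,                   # XLEN=6
           0x42, 0x43, 0x02, 0x00,       # 'B' 'C', SLEN=2
           0x00, 0x00))                  # BSIZE (placeholder)
}

#' Compress one payload into a BGZF member
#'
#' Deflates `payload` (at most 64 KiB) through `backend` and wraps it in
#' BGZF framing: gzip header with the BC/BSIZE extra field, raw deflate
#' data, CRC32 and ISIZE.  Deterministic for a fixed backend and level.  If
#' the backend fails, the default zlib codec takes over for the block with
#' a warning.  In the rare case that an incompressible payload would push
#' BSIZE past its 16-bit bound, the payload is split in half and emitted as
#' two consecutive members (BAM records may span members).
#'
#' @param payload Raw vector, `length(payload) <= 65536`.
#' @param level Deflate compression level (0-9).
#' @param backend Codec `function(payload, level)` returning raw-deflate
#'   bytes; default is the zlib codec.
#' @return Raw vector holding one or more complete BGZF members.
#' @export
bgzf_compress_block <- function(payload, level = 6L, backend = NULL) {
  if (length(payload) > BGZF_MAX_PAYLOAD)
    stop("internal error: BGZF payload exceeds 64 KiB (dispatcher contract)")
  if (is.null(backend)) backend <- zlib_backend
  deflated <- tryCatch(backend(payload, level), error = function(e) {
    warning("compression backend failed (", conditionMessage(e),
            "); falling back to default codec")
    zlib_backend(payload, level)
  })
  member_len <- 18L + length(deflated) + 8L
  if (member_len - 1L > 65535L) {
    half <- length(payload) %/% 2L
    return(c(bgzf_compress_block(payload[seq_len(half)], level, backend),
             bgzf_compress_block(payload[(half + 1L):length(payload)], level,
                                 backend)))
  }
  header <- bgzf_header_template()
  bsize <- member_len - 1L
  header[17:18] <- uint16_le(bsize)
  crc <- .Call(C_crc32, payload)
  c(header, deflated, uint32_le(crc), uint32_le(length(payload)))
}

#' The 28-byte BGZF end-of-file marker
#'
#' A fixed empty BGZF member every conforming writer appends and every
#' reader uses to detect truncation.
#'
#' @return Raw vector of length 28.
#' @export
bgzf_eof <- function() {
  as.raw(c(0x1f, 0x8b, 0x08, 0x04, 0x00, 0x00, 0x00, 0x00, 0x00, 0xff,
           0x06, 0x00, 0x42, 0x43, 0x02, 0x00, 0x1b, 0x00, 0x03, 0x00,
           0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00))
}

#' Enumerate the BGZF members of a byte stream
#'
#' Walks the gzip members of `bytes`, validating the BGZF framing of each:
#' magic, BC extra field, BSIZE, and (when `check_crc`) the CRC32 and ISIZE
#' trailer against the inflated payload.
#'
#' @param bytes Raw vector holding a whole BGZF file.
#' @param check_crc Inflate each member and verify its trailer.
#' @return Data frame with one row per member: `offset` (0-based), `bsize`,
#'   `isize`, `crc_ok`.
#' @export
bgzf_members <- function(bytes, check_crc = TRUE) {
  at <- 0L
  out <- list()
  n <- length(bytes)
  while (at < n) {
    if (at + 18L > n) stop("truncated BGZF member header at offset ", at)
    h <- bytes[(at + 1L):(at + 18L)]
    if (h[1] != as.raw(0x1f) || h[2] != as.raw(0x8b) || h[3] != as.raw(0x08) ||
        h[4] != as.raw(0x04) || h[13] != as.raw(0x42) || h[14] != as.raw(0x43))
      stop("not a BGZF member at offset ", at)
    bsize <- read_uint16(h, 17L)
    member <- bytes[(at + 1L):(at + bsize + 1L)]
    isize <- read_uint32(member, length(member) - 3L)
    crc_ok <- NA
    if (check_crc) {
      deflated <- member[19:(length(member) - 8L)]
      payload <- .Call(C_inflate_raw, deflated, isize)
      crc_ok <- .Call(C_crc32, payload) == read_uint32(member, length(member) - 7L)
    }
    out[[length(out) + 1L]] <- data.frame(offset = at, bsize = bsize,
                                          isize = isize, crc_ok = crc_ok)
    at <- at + bsize + 1L
  }
  do.call(rbind, out)
}

#' Decompress a BGZF file or byte stream
#'
#' @param x Path to a BGZF file, or a raw vector.
#' @return Raw vector of the concatenated uncompressed payloads.
#' @export
bgzf_decompress <- function(x) {
  bytes <- if (is.raw(x)) x else read_file_raw_plain(x)
  at <- 0L
  n <- length(bytes)
  parts <- list()
  while (at < n) {
    h <- bytes[(at + 1L):(at + 18L)]
    bsize <- read_uint16(h, 17L)
    member <- bytes[(at + 1L):(at + bsize + 1L)]
    isize <- read_uint32(member, length(member) - 3L)
    if (isize > 0) {
      deflated <- member[19:(length(member) - 8L)]
      parts[[length(parts) + 1L]] <- .Call(C_inflate_raw, deflated, isize)
    }
    at <- at + bsize + 1L
  }
  do.call(c, c(parts, list(raw(0))))
}

read_file_raw_plain <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = file.size(path))
}
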