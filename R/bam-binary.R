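# BAM binary alignment-record layout, bit-exact per the SAM/BAM
# specification: little-endian fixed header, NUL-terminated read name,
# 28-bit-length CIGAR words, 4-bit packed sequence, raw phred bytes, typed
# optional tags.  encode/decode are exact inverses (the global sequence
# number is bookkeeping and is not serialized).

SEQ_NIBBLE <- strsplit("=ACMGRSVTWYHKDBN", "")[[1]]
CIGAR_CODE <- c(M = 0L, I = 1L, D = 2L, N = 3L, S = 4L, H = 5L, P = 6L,
                `=` = 7L, X = 8L)

int32_le <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

uint16_le <- function(x) as.raw(c(x %% 256L, x %/% 256L))

uint32_le <- function(x) {
  # x may exceed .Machine$integer.max (cigar words); use numeric arithmetic
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, x %/% 16777216))
}

read_uint16 <- function(b, at) as.integer(b[at]) + 256L * as.integer(b[at + 1L])

read_uint32 <- function(b, at) {
  as.numeric(b[at]) + 256 * as.numeric(b[at + 1L]) +
    65536 * as.numeric(b[at + 2L]) + 16777216 * as.numeric(b[at + 3L])
}

read_int32 <- function(b, at) {
  readBin(b[at:(at + 3L)], "integer", size = 4L, endian = "little")
}

# Bin number of the smallest bin containing [beg, end) in the UCSC binning
# scheme used by BAM (14..26-bit levels); unmapped records use bin 4680.
reg2bin <- function(beg, end) {
  if (beg < 0L) return(4680L)
  end <- end - 1L
  if (beg %/% 2^14 == end %/% 2^14) return(as.integer(4681 + beg %/% 2^14))
  if (beg %/% 2^17 == end %/% 2^17) return(as.integer(585 + beg %/% 2^17))
  if (beg %/% 2^20 == end %/% 2^20) return(as.integer(73 + beg %/% 2^20))
  if (beg %/% 2^23 == end %/% 2^23) return(as.integer(9 + beg %/% 2^23))
  if (beg %/% 2^26 == end %/% 2^26) return(as.integer(1 + beg %/% 2^26))
  0L
}

#' Encode an alignment record into BAM binary form
#'
#' Produces the on-disk byte layout of one BAM alignment record, including
#' the leading `block_size` prefix.  `decode_bam_record()` is its exact
#' inverse (minus the global sequence number, which is not serialized).
#'
#' @param rec A `bam_record` from [parse_sam_line()].
#' @return A raw vector.
#' @export
encode_bam_record <- function(rec) {
  name_bytes <- charToRaw(rec$qname)
  l_read_name <- length(name_bytes) + 1L
  if (l_read_name > 255L) stop("read name longer than 254 bytes")
  n_cigar <- length(rec$cigar$op)
  if (any(rec$cigar$len >= 2^28)) stop("CIGAR operation length exceeds 28 bits")
  l_seq <- if (rec$seq == "*") 0L else nchar(rec$seq)
  rlen <- if (n_cigar > 0L)
    max(1L, sum(rec$cigar$len[rec$cigar$op %in% REF_OPS])) else 1L
  bin <- reg2bin(rec$pos, rec$pos + rlen)

  cigar_bytes <- if (n_cigar > 0L) {
    codes <- CIGAR_CODE[rec$cigar$op]
    do.call(c, lapply(seq_len(n_cigar), function(i)
      uint32_le(as.numeric(rec$cigar$len[i]) * 16 + codes[i])))
  } else raw(0)

  seq_bytes <- if (l_seq > 0L) pack_seq(rec$seq) else raw(0)
  qual_bytes <- if (l_seq > 0L) {
    if (is.null(rec$qual)) rep(as.raw(0xff), l_seq) else as.raw(rec$qual)
  } else raw(0)

  tag_bytes <- if (length(rec$tags) > 0L)
    do.call(c, lapply(rec$tags, encode_bam_tag)) else raw(0)

  body <- c(
    int32_le(rec$ref_id), int32_le(rec$pos),
    as.raw(l_read_name), as.raw(rec$mapq), uint16_le(bin),
    uint16_le(n_cigar), uint16_le(rec$flag), int32_le(l_seq),
    int32_le(rec$mate_ref_id), int32_le(rec$mate_pos), int32_le(rec$tlen),
    name_bytes, as.raw(0L),
    cigar_bytes, seq_bytes, qual_bytes, tag_bytes
  )
  c(int32_le(length(body)), body)
}

pack_seq <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], SEQ_NIBBLE)
  if (anyNA(codes))
    stop("sequence contains characters outside the 16-letter nucleotide code")
  codes <- codes - 1L
  if (length(codes) %% 2L == 1L) codes <- c(codes, 0L)
  hi <- codes[seq(1L, length(codes), by = 2L)]
  lo <- codes[seq(2L, length(codes), by = 2L)]
  as.raw(hi * 16L + lo)
}

unpack_seq <- function(bytes, l_seq) {
  v <- as.integer(bytes)
  codes <- as.vector(rbind(v %/% 16L, v %% 16L))[seq_len(l_seq)]
  paste(SEQ_NIBBLE[codes + 1L], collapse = "")
}

encode_bam_tag <- function(t) {
  head <- c(charToRaw(t$tag))
  switch(t$type,
    A = c(head, charToRaw("A"), charToRaw(t$value)),
    i = c(head, charToRaw("i"), int32_le(t$value)),
    f = c(head, charToRaw("f"), writeBin(as.numeric(t$value), raw(), size = 4L,
                                         endian = "little")),
    Z = c(head, charToRaw("Z"), charToRaw(t$value), as.raw(0L)),
    H = c(head, charToRaw("H"), charToRaw(t$value), as.raw(0L)),
    B = {
      sub <- t$value$subtype
      vals <- t$value$values
      body <- switch(sub,
        c = , C = as.raw(vals %% 256),
        s = , S = do.call(c, lapply(vals, function(v)
          if (sub == "s") writeBin(as.integer(v), raw(), size = 2L, endian = "little")
          else uint16_le(as.integer(v)))),
        i = do.call(c, lapply(vals, int32_le)),
        I = do.call(c, lapply(vals, uint32_le)),
        f = writeBin(as.numeric(vals), raw(), size = 4L, endian = "little"),
        stop("unknown B-array subtype: ", sub)
      )
      c(head, charToRaw("B"), charToRaw(sub), int32_le(length(vals)), body)
    },
    stop("unknown tag type: ", t$type)
  )
}

#' Decode a BAM binary alignment record
#'
#' @param bytes Raw vector holding one encoded record (with its `block_size`
#'   prefix), as produced by [encode_bam_record()].
#' @return A `bam_record` (with `gsn = NA`).
#' @export
decode_bam_record <- function(bytes) {
  if (length(bytes) < 36L) stop("truncated BAM record buffer")
  block_size <- read_int32(bytes, 1L)
  if (length(bytes) != block_size + 4L)
    stop("truncated BAM record buffer: block_size ", block_size,
         " but ", length(bytes) - 4L, " bytes present")
  ref_id <- read_int32(bytes, 5L)
  pos <- read_int32(bytes, 9L)
  l_read_name <- as.integer(bytes[13L])
  mapq <- as.integer(bytes[14L])
  n_cigar <- read_uint16(bytes, 17L)
  flag <- read_uint16(bytes, 19L)
  l_seq <- read_int32(bytes, 21L)
  mate_ref_id <- read_int32(bytes, 25L)
  mate_pos <- read_int32(bytes, 29L)
  tlen <- read_int32(bytes, 33L)
  at <- 37L
  if (l_read_name < 1L) stop("inconsistent l_read_name")
  qname <- if (l_read_name > 1L) rawToChar(bytes[at:(at + l_read_name - 2L)]) else ""
  at <- at + l_read_name
  cigar <- list(op = character(0), len = integer(0))
  if (n_cigar > 0L) {
    if (at + 4L * n_cigar - 1L > length(bytes)) stop("inconsistent n_cigar_op count")
    words <- vapply(seq_len(n_cigar), function(i)
      read_uint32(bytes, at + 4L * (i - 1L)), 0)
    cigar <- list(op = names(CIGAR_CODE)[(words %% 16) + 1L],
                  len = as.integer(words %/% 16))
    at <- at + 4L * n_cigar
  }
  seq <- "*"
  qual <- NULL
  if (l_seq > 0L) {
    n_seq_bytes <- (l_seq + 1L) %/% 2L
    seq <- unpack_seq(bytes[at:(at + n_seq_bytes - 1L)], l_seq)
    at <- at + n_seq_bytes
    q <- as.integer(bytes[at:(at + l_seq - 1L)])
    if (!all(q == 255L)) qual <- q
    at <- at + l_seq
  }
  tags <- list()
  while (at <= length(bytes)) {
    dec <- decode_bam_tag(bytes, at)
    tags[[length(tags) + 1L]] <- dec$tag
    at <- dec$at
  }
  structure(list(
    qname = qname, flag = flag, ref_id = ref_id, pos = pos, mapq = mapq,
    cigar = cigar, mate_ref_id = mate_ref_id, mate_pos = mate_pos,
    tlen = tlen, seq = seq, qual = qual, tags = tags, gsn = NA_integer_
  ), class = "bam_record")
}

decode_bam_tag <- function(b, at) {
  if (at + 2L > length(b)) stop("truncated tag block")
  tag <- rawToChar(b[at:(at + 1L)])
  type <- rawToChar(b[at + 2L])
  at <- at + 3L
  read_scalar <- function(type, at) {
    switch(type,
      c = list(v = readBin(b[at], "integer", size = 1L, signed = TRUE), n = 1L),
      C = list(v = as.integer(b[at]), n = 1L),
      s = list(v = readBin(b[at:(at + 1L)], "integer", size = 2L,
                           endian = "little"), n = 2L),
      S = list(v = read_uint16(b, at), n = 2L),
      i = list(v = read_int32(b, at), n = 4L),
      I = list(v = read_uint32(b, at), n = 4L),
      f = list(v = readBin(b[at:(at + 3L)], "double", size = 4L,
                           endian = "little"), n = 4L),
      stop("unknown tag value type: ", type)
    )
  }
  if (type %in% c("c", "C", "s", "S", "i", "I")) {
    s <- read_scalar(type, at)
    # all integer widths surface as SAM type 'i'
    list(tag = list(tag = tag, type = "i", value = as.integer(s$v)), at = at + s$n)
  } else if (type == "f") {
    s <- read_scalar("f", at)
    list(tag = list(tag = tag, type = "f", value = s$v), at = at + 4L)
  } else if (type == "A") {
    list(tag = list(tag = tag, type = "A", value = rawToChar(b[at])), at = at + 1L)
  } else if (type %in% c("Z", "H")) {
    nul <- at
    while (nul <= length(b) && b[nul] != as.raw(0L)) nul <- nul + 1L
    if (nul > length(b)) stop("unterminated ", type, " tag")
    val <- if (nul > at) rawToChar(b[at:(nul - 1L)]) else ""
    list(tag = list(tag = tag, type = type, value = val), at = nul + 1L)
  } else if (type == "B") {
    sub <- rawToChar(b[at])
    count <- read_int32(b, at + 1L)
    at <- at + 5L
    vals <- numeric(count)
    for (i in seq_len(count)) {
      s <- read_scalar(sub, at)
      vals[i] <- s$v
      at <- at + s$n
    }
    list(tag = list(tag = tag, type = "B",
                    value = list(subtype = sub, values = vals)), at = at)
  } else stop("unknown tag type: ", type)
}

# Byte offsets of the FLAG field within an encoded record (after the 4-byte
# block_size prefix the fixed header puts flag at bytes 14-15, i.e. absolute
# offsets 19-20 in 1-based indexing).  Used to apply the duplicate flag at
# write time without re-encoding.
patch_flag_duplicate <- function(bytes) {
  flag <- read_uint16(bytes, 19L)
  flag <- bitwOr(flag, FLAG_DUPLICATE)
  bytes[19L:20L] <- uint16_le(flag)
  bytes
}
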