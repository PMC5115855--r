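# Stage 3: parse SAM lines into binary alignment records (the in-memory
# analogue of htslib's bam1_t), plus the CIGAR-derived geometry used by the
# alignment database and the duplicate-marking analyzer.
#
# Coordinates are 0-based half-open internally; SAM text I/O converts to and
# from 1-based.  '=' and 'X' are treated exactly as 'M' for reference/query
# accounting.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")
REF_OPS   <- c("M", "D", "N", "=", "X")

# SAM FLAG bits
FLAG_PAIRED        <- 0x1L
FLAG_UNMAPPED      <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE       <- 0x10L
FLAG_MATE_REVERSE  <- 0x20L
FLAG_SECONDARY     <- 0x100L
FLAG_DUPLICATE     <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

#' Parse one SAM alignment line into a binary alignment record
#'
#' Captures the 11 mandatory fields and all optional tags.  SAM's 1-based
#' `POS`/`PNEXT` become 0-based `pos`/`mate_pos` (`-1` when the field is
#' `*`/`0`), `RNAME`/`RNEXT` are resolved to 0-based reference ids against
#' the header, and base qualities become phred integers (ASCII − 33).
#'
#' @param line A tab-separated SAM alignment line (no trailing newline).
#' @param header A [parse_sam_header()] result used to resolve reference names.
#' @param gsn Global sequence number assigned to the record: the per-file
#'   ordinal of first appearance, used downstream for stable ordering and
#'   duplicate tie-breaking.
#' @return A list of class `bam_record` with fields `qname`, `flag`,
#'   `ref_id`, `pos`, `mapq`, `cigar` (list of `op`, `len` vectors),
#'   `mate_ref_id`, `mate_pos`, `tlen`, `seq`, `qual` (integer phred vector
#'   or `NULL`), `tags` (list of `tag`/`type`/`value`), `gsn`.
#' @export
parse_sam_line <- function(line, header, gsn = 0L) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11L)
    stop("SAM parse error (gsn ", gsn, "): expected >= 11 fields, got ", length(f))
  flag <- suppressWarnings(as.integer(f[2]))
  if (is.na(flag) || flag < 0L || flag > 65535L)
    stop("SAM parse error (gsn ", gsn, "): FLAG is not a 16-bit integer: ", f[2])
  pos1 <- suppressWarnings(as.integer(f[4]))
  if (is.na(pos1) || pos1 < 0L)
    stop("SAM parse error (gsn ", gsn, "): POS is not a nonnegative integer: ", f[4])
  mapq <- suppressWarnings(as.integer(f[5]))
  if (is.na(mapq) || mapq < 0L || mapq > 255L)
    stop("SAM parse error (gsn ", gsn, "): MAPQ out of range: ", f[5])
  ref_id <- tryCatch(ref_id_of(f[3], header), error = function(e)
    stop("SAM parse error (gsn ", gsn, "): ", conditionMessage(e)))
  mate_rname <- f[7]
  mate_ref_id <- if (mate_rname == "=") ref_id else tryCatch(
    ref_id_of(mate_rname, header), error = function(e)
      stop("SAM parse error (gsn ", gsn, "): ", conditionMessage(e)))
  pnext1 <- suppressWarnings(as.integer(f[8]))
  if (is.na(pnext1))
    stop("SAM parse error (gsn ", gsn, "): PNEXT is not an integer: ", f[8])
  tlen <- suppressWarnings(as.integer(f[9]))
  if (is.na(tlen))
    stop("SAM parse error (gsn ", gsn, "): TLEN is not an integer: ", f[9])
  cigar <- tryCatch(parse_cigar(f[6]), error = function(e)
    stop("SAM parse error (gsn ", gsn, "): ", conditionMessage(e)))
  seq <- f[10]
  qual <- if (f[11] == "*") NULL else as.integer(charToRaw(f[11])) - 33L
  if (seq != "*" && length(cigar$op) > 0L) {
    qlen <- sum(cigar$len[cigar$op %in% QUERY_OPS])
    if (qlen != nchar(seq))
      stop("SAM parse error (gsn ", gsn, "): CIGAR query length ", qlen,
           " != SEQ length ", nchar(seq))
  }
  tags <- if (length(f) > 11L) lapply(f[-(1:11)], parse_sam_tag, gsn = gsn) else list()
  structure(list(
    qname = f[1], flag = flag, ref_id = ref_id, pos = pos1 - 1L, mapq = mapq,
    cigar = cigar, mate_ref_id = mate_ref_id, mate_pos = pnext1 - 1L,
    tlen = tlen, seq = seq, qual = qual, tags = tags, gsn = as.integer(gsn)
  ), class = "bam_record")
}

parse_cigar <- function(text) {
  if (text == "*") return(list(op = character(0), len = integer(0)))
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", text))
    stop("malformed CIGAR: ", text)
  lens <- as.integer(regmatches(text, gregexpr("[0-9]+", text))[[1]])
  ops <- regmatches(text, gregexpr("[MIDNSHP=X]", text))[[1]]
  if (any(lens <= 0L)) stop("malformed CIGAR (zero-length op): ", text)
  list(op = ops, len = lens)
}

format_cigar <- function(cigar) {
  if (length(cigar$op) == 0L) "*" else paste0(cigar$len, cigar$op, collapse = "")
}

parse_sam_tag <- function(field, gsn = 0L) {
  m <- regmatches(field, regexec("^([A-Za-z][A-Za-z0-9]):([AifZHB]):?(.*)$", field))[[1]]
  if (length(m) == 0L)
    stop("SAM parse error (gsn ", gsn, "): malformed optional tag: ", field)
  tag <- m[2]; type <- m[3]; raw_val <- m[4]
  value <- switch(type,
    A = raw_val,
    i = {
      v <- suppressWarnings(as.integer(raw_val))
      if (is.na(v)) stop("SAM parse error (gsn ", gsn, "): non-integer i tag: ", field)
      v
    },
    f = as.numeric(raw_val),
    Z = raw_val,
    H = raw_val,
    B = {
      parts <- strsplit(raw_val, ",", fixed = TRUE)[[1]]
      list(subtype = parts[1], values = as.numeric(parts[-1]))
    }
  )
  list(tag = tag, type = type, value = value)
}

format_sam_tag <- function(t) {
  val <- switch(t$type,
    B = paste(c(t$value$subtype, format_tag_num(t$value$values)), collapse = ","),
    f = format_tag_num(t$value),
    as.character(t$value)
  )
  paste(t$tag, t$type, val, sep = ":")
}

format_tag_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE), as.character(x))
}

get_tag <- function(rec, tag) {
  for (t in rec$tags) if (t$tag == tag) return(t)
  NULL
}

#' Format a binary alignment record back to SAM text
#'
#' Inverse of [parse_sam_line()]; `format_sam_line(parse_sam_line(x))`
#' reproduces `x` for canonical lines.
#'
#' @param rec A `bam_record`.
#' @param header The header used to render reference names.
#' @return A single SAM line (no newline).
#' @export
format_sam_line <- function(rec, header) {
  rnext <- if (rec$mate_ref_id < 0L) "*"
           else if (rec$mate_ref_id == rec$ref_id && rec$ref_id >= 0L) "="
           else ref_name_of(rec$mate_ref_id, header)
  fields <- c(
    rec$qname, rec$flag, ref_name_of(rec$ref_id, header), rec$pos + 1L,
    rec$mapq, format_cigar(rec$cigar), rnext, rec$mate_pos + 1L, rec$tlen,
    rec$seq,
    if (is.null(rec$qual)) "*" else rawToChar(as.raw(rec$qual + 33L))
  )
  tags <- vapply(rec$tags, format_sam_tag, "")
  paste(c(fields, tags), collapse = "\t")
}

clip_lengths <- function(cigar) {
  n <- length(cigar$op)
  lead <- 0L
  i <- 1L
  while (i <= n && cigar$op[i] %in% c("S", "H")) {
    lead <- lead + cigar$len[i]; i <- i + 1L
  }
  trail <- 0L
  i <- n
  while (i >= 1L && cigar$op[i] %in% c("S", "H")) {
    trail <- trail + cigar$len[i]; i <- i - 1L
  }
  c(lead = lead, trail = trail)
}

#' Alignment geometry of a mapped record
#'
#' `alignment_end()` is the 0-based inclusive rightmost reference coordinate
#' (`pos` + reference-consuming CIGAR length − 1).  `unclipped_start()` and
#' `unclipped_end()` restore leading/trailing soft and hard clips;
#' `unclipped_5prime()` is the coordinate the read's 5' end would occupy had
#' no clipping occurred — the key under which PCR duplicates coincide:
#' `unclipped_start` on the forward strand, `unclipped_end` on the reverse.
#' Unclipped coordinates may be negative; they are kept, not clamped.
#'
#' @param rec A mapped `bam_record` with a nonempty CIGAR.
#' @return An integer coordinate.
#' @export
alignment_end <- function(rec) {
  stopifnot(rec$ref_id >= 0L, length(rec$cigar$op) > 0L)
  rlen <- sum(rec$cigar$len[rec$cigar$op %in% REF_OPS])
  rec$pos + rlen - 1L
}

#' @rdname alignment_end
#' @export
unclipped_start <- function(rec) {
  rec$pos - clip_lengths(rec$cigar)[["lead"]]
}

#' @rdname alignment_end
#' @export
unclipped_end <- function(rec) {
  alignment_end(rec) + clip_lengths(rec$cigar)[["trail"]]
}

#' @rdname alignment_end
#' @export
unclipped_5prime <- function(rec) {
  if (bitwAnd(rec$flag, FLAG_REVERSE) != 0L) unclipped_end(rec) else unclipped_start(rec)
}

#' Summarized base-quality score of a record
#'
#' Sum of phred base qualities at or above `min_q`, the representative-
#' selection score used by duplicate marking (Picard-compatible; default
#' threshold 15).  Records without base qualities score 0.
#'
#' @param rec A `bam_record`.
#' @param min_q Minimum phred value a base must reach to count.
#' @return Nonnegative integer score.
#' @export
quality_score_sum <- function(rec, min_q = 15L) {
  if (is.null(rec$qual)) return(0L)
  q <- rec$qual[rec$qual >= min_q]
  as.integer(sum(q))
}
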