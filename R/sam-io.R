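#' @useDynLib pipebam, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# Stage 1-2 of the pipeline: read a SAM file as data blocks whose boundaries
# are adjusted backwards to line boundaries, then split each block into line
# offsets.  Blocks are self-contained (no line spans two blocks), which is
# what lets later stages process blocks independently.

NL <- as.raw(10L)
CR <- as.raw(13L)

#' Read a SAM file into line-aligned data blocks
#'
#' Reads `path` (plain or gzip-compressed, sniffed from the magic bytes),
#' consumes the `@`-prefixed header lines eagerly, and chops the remaining
#' alignment body into blocks of at most `block_size` bytes.  Each block is
#' truncated backwards to the last newline it contains, and the carried-over
#' tail starts the next block, so every block ends at a SAM line boundary
#' (the final block may lack a trailing newline).
#'
#' @param path Path to a SAM file.
#' @param block_size Maximum block payload in bytes (default 64 KiB).
#' @return A list with `header` (a [sam_header] object), `header_text`,
#'   and `blocks`, a list of data blocks; each block is a list with
#'   `block_number` (0-based, consecutive), `payload` (raw vector) and
#'   `line_offsets` (`NULL` until [split_lines()] fills it).
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
#'   "r1\t0\tchr1\t100\t60\t4M\t*\t0\t0\tACGT\tIIII"), sam)
#' rd <- read_sam_blocks(sam)
#' length(rd$blocks)
#' @export
read_sam_blocks <- function(path, block_size = 65536L) {
  stopifnot(length(path) == 1L, file.exists(path), block_size >= 1L)
  body <- read_file_raw(path)
  split <- split_off_header(body)
  header <- parse_sam_header(split$header_text)
  list(
    header = header,
    header_text = split$header_text,
    blocks = chop_blocks(split$body, as.integer(block_size))
  )
}

# Whole-file raw read with gzip sniffing ('\x1f\x8b').
read_file_raw <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 2L)
  close(con)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    con <- gzcon(file(path, "rb"))
    on.exit(close(con))
    chunks <- list()
    repeat {
      chunk <- readBin(con, "raw", n = 1048576L)
      if (length(chunk) == 0L) break
      chunks[[length(chunks) + 1L]] <- chunk
    }
    do.call(c, c(chunks, list(raw(0))))
  } else {
    n <- file.size(path)
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = n)
  }
}

# Header lines are consumed before streaming begins; alignment blocks never
# contain header lines.  Returns the header text and the remaining body.
split_off_header <- function(body) {
  at <- 0L
  n <- length(body)
  while (at < n && body[at + 1L] == as.raw(64L)) {  # '@'
    nl <- match(TRUE, body[(at + 1L):n] == NL)
    if (is.na(nl)) { at <- n; break }
    at <- at + nl
  }
  header_text <- if (at > 0L) rawToChar(body[seq_len(at)]) else ""
  list(header_text = header_text, body = if (at < n) body[(at + 1L):n] else raw(0))
}

chop_blocks <- function(body, block_size) {
  blocks <- list()
  pos <- 0L
  n <- length(body)
  bn <- 0L
  while (pos < n) {
    hi <- min(pos + block_size, n)
    payload <- body[(pos + 1L):hi]
    if (hi < n) {
      # scan from the end to the beginning for the last newline
      nl_at <- last_newline(payload)
      if (is.na(nl_at)) {
        stop("line exceeds block size (", block_size, " bytes) at byte offset ",
             pos, "; increase block_size")
      }
      payload <- payload[seq_len(nl_at)]
    }
    blocks[[bn + 1L]] <- list(block_number = bn, payload = payload,
                              line_offsets = NULL)
    pos <- pos + length(payload)
    bn <- bn + 1L
  }
  blocks
}

last_newline <- function(payload) {
  hits <- which(payload == NL)
  if (length(hits) == 0L) NA_integer_ else hits[length(hits)]
}

#' Split a data block into SAM line offsets
#'
#' Scans the block payload from beginning to end for newline characters and
#' records the 0-based start offset of every line.  A final line without a
#' trailing newline is counted as a complete line.
#'
#' @param block A data block from [read_sam_blocks()].
#' @return The block with `line_offsets` populated (0-based, strictly
#'   increasing).
#' @export
split_lines <- function(block) {
  payload <- block$payload
  if (length(payload) == 0L) {
    block$line_offsets <- integer(0)
    return(block)
  }
  nls <- which(payload == NL)
  starts <- c(0L, nls)                 # byte after each newline starts a line
  starts <- starts[starts < length(payload)]
  block$line_offsets <- as.integer(starts)
  block
}

#' Extract the text lines of a split block
#'
#' Materializes the SAM lines a block's `line_offsets` point at; trailing
#' `\r` is stripped so CRLF input parses identically to LF input.
#'
#' @param block A block processed by [split_lines()].
#' @return Character vector of SAM lines.
#' @export
block_lines <- function(block) {
  if (is.null(block$line_offsets))
    stop("block has not been through split_lines()")
  offs <- block$line_offsets
  if (length(offs) == 0L) return(character(0))
  txt <- rawToChar(block$payload)
  ends <- c(offs[-1L], length(block$payload))
  lines <- substring(txt, offs + 1L, ends)
  lines <- sub("\r?\n?$", "", lines)
  lines
}

#' Parse SAM header text
#'
#' Extracts the reference-sequence dictionary (`@SQ` lines, in file order —
#' this order defines the BAM reference ids) and read groups (`@RG`, with
#' their `LB` library names used to partition duplicate detection).
#'
#' @param text Raw header text (may be empty).
#' @return An object of class `sam_header`: a list with `text`, `sequences`
#'   (data frame `name`, `length`) and `read_groups` (data frame `id`,
#'   `library`, `library_id`).
#' @export
parse_sam_header <- function(text) {
  lines <- if (nzchar(text)) strsplit(text, "\n", fixed = TRUE)[[1]] else character(0)
  lines <- sub("\r$", "", lines)
  sq <- grep("^@SQ\t", lines, value = TRUE)
  get_field <- function(line, tag) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]][-1]
    hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
    if (length(hit) == 0L) NA_character_ else substring(hit[1], 4L)
  }
  sequences <- data.frame(
    name = vapply(sq, get_field, "", tag = "SN", USE.NAMES = FALSE),
    length = as.integer(vapply(sq, get_field, "", tag = "LN", USE.NAMES = FALSE)),
    stringsAsFactors = FALSE
  )
  if (anyNA(sequences$name) || anyDuplicated(sequences$name))
    stop("malformed @SQ lines: missing or duplicate SN")
  rg <- grep("^@RG\t", lines, value = TRUE)
  ids <- vapply(rg, get_field, "", tag = "ID", USE.NAMES = FALSE)
  libs <- vapply(rg, get_field, "", tag = "LB", USE.NAMES = FALSE)
  libs[is.na(libs)] <- ids[is.na(libs)]
  read_groups <- data.frame(
    id = ids, library = libs,
    library_id = if (length(libs)) as.integer(factor(libs, levels = unique(libs))) else integer(0),
    stringsAsFactors = FALSE
  )
  structure(
    list(text = text, sequences = sequences, read_groups = read_groups),
    class = "sam_header"
  )
}

#' @export
print.sam_header <- function(x, ...) {
  cat("SAM header:", nrow(x$sequences), "reference sequence(s),",
      nrow(x$read_groups), "read group(s)\n")
  invisible(x)
}

# ref name -> 0-based id (-1 for '*')
ref_id_of <- function(name, header) {
  if (name == "*") return(-1L)
  id <- match(name, header$sequences$name)
  if (is.na(id)) stop("unknown reference sequence name: ", name)
  id - 1L
}

ref_name_of <- function(ref_id, header) {
  if (ref_id < 0L) "*" else header$sequences$name[ref_id + 1L]
}
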