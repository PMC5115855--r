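# Stage 4: record virtualization.  Binary alignment records are placed
# either in main memory (memory mode) or appended to a spill file in
# external storage (storage mode); both are addressed uniformly through
# virtual addresses, so every downstream stage is oblivious to the mode.
# Records are immutable once stored; the duplicate flag is applied at write
# time from the alignment database, never by in-place mutation.

#' Open a record store
#'
#' @param mode `"memory"` (records resident as raw vectors) or `"storage"`
#'   (records appended to a spill file; the address is the byte offset).
#' @param spill_dir Directory for the spill file in storage mode; must be
#'   writable at open time (failure surfaces here, not mid-run).
#' @return An environment of class `record_store`.
#' @export
record_store <- function(mode = c("memory", "storage"), spill_dir = tempdir()) {
  mode <- match.arg(mode)
  s <- new.env(parent = emptyenv())
  s$mode <- mode
  s$n <- 0L
  if (mode == "memory") {
    s$slots <- vector("list", 1024L)
  } else {
    if (!dir.exists(spill_dir) || file.access(spill_dir, 2L) != 0L)
      stop("spill directory is not writable: ", spill_dir)
    s$spill_path <- tempfile("pipebam-spill-", tmpdir = spill_dir, fileext = ".bin")
    s$con <- file(s$spill_path, "w+b")
    s$offset <- 0
  }
  class(s) <- "record_store"
  s
}

#' Store an alignment record, returning its virtual address
#'
#' @param s A [record_store()].
#' @param rec A `bam_record`, or a raw vector already in encoded form.
#' @return A `virtual_address`: list with `mode`, `offset` (memory slot index
#'   or spill-file byte offset, 0-based) and `size` (encoded byte length).
#' @export
store_record <- function(s, rec) {
  bytes <- if (is.raw(rec)) rec else encode_bam_record(rec)
  size <- length(bytes)
  if (s$mode == "memory") {
    s$n <- s$n + 1L
    if (s$n > length(s$slots)) s$slots <- c(s$slots, vector("list", length(s$slots)))
    s$slots[[s$n]] <- bytes
    va <- list(mode = "memory", offset = s$n - 1L, size = size)
  } else {
    seek(s$con, where = s$offset, rw = "write")
    writeBin(bytes, s$con)
    va <- list(mode = "storage", offset = s$offset, size = size)
    s$offset <- s$offset + size
    s$n <- s$n + 1L
  }
  structure(va, class = "virtual_address")
}

#' Fetch the encoded bytes behind a virtual address
#'
#' @param s The store that issued `va`.
#' @param va A `virtual_address`.
#' @return Raw vector of `va$size` bytes.
#' @export
fetch_bytes <- function(s, va) {
  if (!inherits(va, "virtual_address") || va$mode != s$mode)
    stop("virtual address does not belong to this store")
  if (s$mode == "memory") {
    idx <- va$offset + 1L
    if (idx < 1L || idx > s$n) stop("unknown virtual address (slot ", va$offset, ")")
    bytes <- s$slots[[idx]]
    if (length(bytes) != va$size) stop("unknown virtual address (size mismatch)")
    bytes
  } else {
    if (va$offset + va$size > s$offset)
      stop("unknown virtual address (beyond spill file end)")
    flush(s$con)
    seek(s$con, where = va$offset, rw = "read")
    readBin(s$con, "raw", n = va$size)
  }
}

#' Fetch and decode the record behind a virtual address
#'
#' @inheritParams fetch_bytes
#' @return A `bam_record`.
#' @export
fetch_record <- function(s, va) {
  decode_bam_record(fetch_bytes(s, va))
}

#' Encoded size of a stored record
#'
#' Available from the address alone, without touching the record body — this
#' is what lets the block dispatcher pack records into 64-KiB blocks without
#' copying any data.
#'
#' @inheritParams fetch_bytes
#' @return Integer byte length.
#' @export
record_size <- function(s, va) {
  if (!inherits(va, "virtual_address")) stop("not a virtual address")
  if (s$n == 0L) stop("store is empty; no records have been stored")
  va$size
}

#' Number of records in the store
#' @param s A record store.
#' @return Integer count.
#' @export
store_count <- function(s) s$n

#' Close a record store, deleting the spill file
#'
#' Memory-mode stores release their slots; storage-mode stores close and
#' remove the spill file (on a crash the file is left behind for diagnosis
#' because this is only reached on the normal path).
#'
#' @param s A record store.
#' @export
close_store <- function(s) {
  if (s$mode == "storage") {
    try(close(s$con), silent = TRUE)
    unlink(s$spill_path)
  } else {
    s$slots <- list()
  }
  s$n <- 0L
  invisible(NULL)
}

#' @export
print.record_store <- function(x, ...) {
  cat("record store (", x$mode, " mode): ", x$n, " record(s)\n", sep = "")
  invisible(x)
}
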