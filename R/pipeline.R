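# Pipeline orchestration.  The staged design: (1) block reading with
# line-boundary adjustment, (2) line splitting, (3) SAM parsing with global
# sequence numbers, (4) record virtualization, (5) alignment-database
# construction, (6) analyzer execution over segmented regions, (7) block
# dispatch, compression and ordered write.  Without analyzers, records flow
# 1 -> 4 -> 7 directly (stages 5-6 are skipped) and only memory mode is
# permitted; with analyzers, all input pools in the database first and the
# writer traverses it in sort order.
#
# Every stage is an ordered map over independent units (blocks, then
# records, then regions, then BAM blocks), so results are identical for any
# worker configuration; workers only set how many compression units run
# concurrently.

#' Build a pipeline configuration
#'
#' @param input Path to a SAM file (plain or gzip-compressed).
#' @param output Path for the BAM output.
#' @param mode Record virtualization mode, `"memory"` or `"storage"`.
#'   Storage mode requires at least one analyzer (streaming runs keep
#'   records in memory only, matching the staged design).
#' @param block_size SAM read-block size in bytes.
#' @param workers Worker count: a single integer applied to every scalable
#'   stage, or a named list with any of `parse`, `analyze`, `compress`.
#' @param filters Character vector of filter specs, e.g.
#'   `"region=chr1:1000-2000"` (1-based closed).
#' @param analyzers Character vector of analyzer plug-in names, e.g.
#'   `"dupmark"`.
#' @param compression_level Deflate level 0-9.
#' @param spill_dir Spill directory for storage mode.
#' @param backend Compression backend name(s) from the registry (default
#'   `"zlib"`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output, mode = c("memory", "storage"),
                            block_size = 65536L, workers = 1L,
                            filters = character(0), analyzers = character(0),
                            compression_level = 6L, spill_dir = tempdir(),
                            backend = "zlib") {
  mode <- match.arg(mode)
  if (is.numeric(workers)) {
    workers <- list(parse = as.integer(workers), analyze = as.integer(workers),
                    compress = as.integer(workers))
  }
  workers <- utils::modifyList(list(parse = 1L, analyze = 1L, compress = 1L),
                               workers)
  if (any(unlist(workers) < 1L)) stop("worker counts must be >= 1")
  if (mode == "storage" && length(analyzers) == 0L)
    stop("storage mode requires an analyzer; streaming runs enable memory mode only")
  for (a in analyzers) lookup_plugin("analyzers", a)
  for (b in backend) lookup_plugin("backends", b)
  structure(list(
    input = input, output = output, mode = mode,
    block_size = as.integer(block_size), workers = workers,
    filters = filters, analyzers = analyzers,
    compression_level = as.integer(compression_level),
    spill_dir = spill_dir, backend = backend
  ), class = "pipeline_config")
}

#' Run the conversion pipeline
#'
#' Executes the staged SAM-to-BAM conversion described in
#' [pipeline_config()].  With analyzers the output is coordinate-sorted and
#' carries analyzer results (e.g. duplicate flags); without analyzers the
#' input record order is preserved.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage progress to `message()`.
#' @return A list of class `pipebam_summary`: `records_in`,
#'   `records_filtered`, `records_out`, `duplicates_marked`,
#'   `blocks_written`, `output`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[pipebam] ", ...)
  t0 <- proc.time()[["elapsed"]]

  # stages 1-2: blocks + line offsets
  rd <- read_sam_blocks(config$input, config$block_size)
  header <- rd$header
  blocks <- lapply(rd$blocks, split_lines)
  say("read ", length(blocks), " block(s)")

  filters <- build_filters(config$filters, header)
  analyzers <- lapply(config$analyzers, lookup_plugin, kind = "analyzers")
  with_db <- length(analyzers) > 0L
  wants_unclipped <- any(vapply(analyzers, function(a)
    isTRUE(a$wants_unclipped_index), TRUE))

  store <- record_store(config$mode, config$spill_dir)
  on.exit(close_store(store))
  db <- if (with_db) alignment_db(with_unclipped = wants_unclipped)

  # stage 3-5: parse, filter, virtualize, pool
  records_in <- 0L
  records_filtered <- 0L
  stream <- list()
  for (block in blocks) {
    for (line in block_lines(block)) {
      rec <- parse_sam_line(line, header, gsn = records_in)
      records_in <- records_in + 1L
      if (!apply_filters(rec, filters)) {
        records_filtered <- records_filtered + 1L
        next
      }
      va <- store_record(store, rec)
      if (with_db) {
        db_insert(db, build_baminfo(rec, va, header), qname = rec$qname)
      } else {
        stream[[length(stream) + 1L]] <- va
      }
    }
  }
  say("parsed ", records_in, " record(s), filtered ", records_filtered)

  # stage 6: analyzers over segmented unclipped-position regions
  duplicates_marked <- 0L
  if (with_db) {
    resolve_mates(db)
    regions <- segment_regions(db, config$workers$analyze)
    for (a in analyzers) {
      for (region in regions) {
        res <- a$analyze(db, region)
        if (is.numeric(res)) duplicates_marked <- duplicates_marked + res
      }
    }
    say("analyzers done: ", duplicates_marked, " duplicate(s) marked")
  }

  # stage 7: dispatch, compress, ordered write
  backends <- lapply(config$backend, lookup_plugin, kind = "backends")
  res <- write_bam(store, header, config$output,
                   db = if (with_db) db else NULL,
                   stream = if (!with_db) stream else NULL,
                   workers = config$workers$compress,
                   level = config$compression_level,
                   backend = backends)
  say("wrote ", res$n_blocks, " BAM block(s) in ",
      round(proc.time()[["elapsed"]] - t0, 2), "s")

  structure(list(
    records_in = records_in,
    records_filtered = records_filtered,
    records_out = res$n_records,
    duplicates_marked = as.integer(duplicates_marked),
    blocks_written = res$n_blocks,
    output = res$path
  ), class = "pipebam_summary")
}

#' @export
print.pipebam_summary <- function(x, ...) {
  cat("pipebam conversion summary\n",
      "  records in:        ", x$records_in, "\n",
      "  records filtered:  ", x$records_filtered, "\n",
      "  records out:       ", x$records_out, "\n",
      "  duplicates marked: ", x$duplicates_marked, "\n",
      "  BAM blocks:        ", x$blocks_written, "\n",
      "  output:            ", x$output, "\n", sep = "")
  invisible(x)
}
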