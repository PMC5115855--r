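# The baminfo alignment database: compact entries, position arrangements,
# mate resolution, sorted traversal, region segmentation.

db_of <- function(lines, with_unclipped = TRUE, header = test_header()) {
  s <- record_store("memory")
  db <- alignment_db(with_unclipped = with_unclipped)
  for (i in seq_along(lines)) {
    rec <- parse_sam_line(lines[i], header, gsn = i - 1L)
    va <- store_record(s, rec)
    db_insert(db, build_baminfo(rec, va, header), qname = rec$qname)
  }
  resolve_mates(db)
  list(db = db, store = s)
}

test_that("baminfo summarizes the record and carries no long strings", {
  h <- test_header()
  rec <- mk_rec(pos = 300L, cigar = "4M", flag = 0L,
                qual = rawToChar(as.raw(c(20L, 10L, 30L, 40L) + 33L)),
                tags = "RG:Z:rg2")
  s <- record_store("memory")
  info <- build_baminfo(rec, store_record(s, rec), h)
  expect_identical(info$clipped_pos, rec$pos)
  expect_identical(info$unclipped_5prime, rec$pos)  # zero-clip identity
  expect_identical(info$score, 90L)
  expect_identical(info$library_id, 2L)             # rg2 -> libB
  # structurally: no character field longer than a mode tag
  chars <- Filter(is.character, info)
  expect_true(all(nchar(unlist(chars)) <= 8L))
  expect_false(any(c("qname", "seq", "qual", "cigar", "tags") %in% names(info)))
})

test_that("unknown read groups warn and fall back to the default library", {
  h <- test_header()
  rec <- mk_rec(tags = "RG:Z:nope")
  s <- record_store("memory")
  expect_warning(info <- build_baminfo(rec, store_record(s, rec), h),
                 "unknown read group")
  expect_identical(info$library_id, 0L)
})

test_that("grouped lookup returns co-positioned entries in gsn order", {
  lines <- c(
    sam_line(qname = "a", pos = 500L),
    sam_line(qname = "b", pos = 900L),
    sam_line(qname = "c", pos = 500L),
    sam_line(qname = "d", pos = 500L)
  )
  x <- db_of(lines)
  got <- lookup_clipped(x$db, 0L, 499L)
  expect_identical(vapply(got, function(i) i$gsn, 0L), c(0L, 2L, 3L))
  expect_length(lookup_clipped(x$db, 0L, 12345L), 0L)
})

test_that("clipped and unclipped arrangements key the same record differently", {
  L <- strrep("A", 100); q <- strrep("I", 100)
  lines <- sam_line(qname = "clip", pos = 1000L, cigar = "3S97M",
                    seq = L, qual = q)
  x <- db_of(lines)
  expect_length(lookup_clipped(x$db, 0L, 999L), 1L)
  expect_length(lookup_unclipped(x$db, 0L, 996L), 1L)
  expect_length(lookup_unclipped(x$db, 0L, 999L), 0L)
})

test_that("the unclipped arrangement must be requested to be queried", {
  x <- db_of(sam_line(), with_unclipped = FALSE)
  expect_error(lookup_unclipped(x$db, 0L, 99L), "not requested")
})

test_that("sorted traversal equals an independent comparison sort", {
  set.seed(17)
  n <- 2000L
  lines <- vapply(seq_len(n), random_sam_line, "")
  # a few unmapped stragglers and ties
  lines <- c(lines, "u1\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
             sam_line(qname = "tie1", pos = 777L),
             "u2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
             sam_line(qname = "tie2", pos = 777L))
  x <- db_of(lines)
  out <- traverse_sorted(x$db)
  expect_length(out, length(lines))   # cardinality conservation
  keys <- data.frame(
    unmapped = vapply(out, function(i) i$ref_id < 0L, TRUE),
    ref = vapply(out, function(i) i$ref_id, 0L),
    pos = vapply(out, function(i) i$clipped_pos, 0L),
    gsn = vapply(out, function(i) i$gsn, 0L)
  )
  oracle <- keys[order(keys$unmapped, keys$ref, keys$pos, keys$gsn), ]
  expect_identical(keys, structure(oracle, row.names = seq_len(nrow(keys))))
  # unmapped emitted last, in gsn order
  expect_true(all(which(keys$unmapped) > sum(!keys$unmapped)))
  # records at identical coordinates keep input order
  ties <- keys[keys$pos == 776L & keys$ref == 0L & !keys$unmapped, ]
  expect_false(is.unsorted(ties$gsn))
})

test_that("mate resolution fills pair scores via MC tags and the side table", {
  q1 <- rawToChar(as.raw(rep(30L, 4L) + 33L))
  q2 <- rawToChar(as.raw(rep(20L, 4L) + 33L))
  mk_pair <- function(name, with_mc) {
    mc1 <- if (with_mc) "\tMC:Z:4M" else ""
    c(paste0(name, "\t99\tchr1\t100\t60\t4M\t=\t300\t204\tACGT\t", q1, mc1),
      paste0(name, "\t147\tchr1\t300\t60\t4M\t=\t100\t-204\tACGT\t", q2, mc1))
  }
  x <- db_of(c(mk_pair("mc", TRUE), mk_pair("side", FALSE)))
  infos <- traverse_sorted(x$db)
  for (info in infos) {
    expect_identical(info$pair_score, 200L)
    # forward mate at pos 99 (0-based): unclipped 5' 99; reverse mate: 302
    expect_true(info$mate_unclipped_5prime %in% c(99L, 302L))
    expect_false(is.na(info$mate_gsn))
  }
})

test_that("segment_regions partitions the occupied key space atomically", {
  set.seed(23)
  fx <- generate_fixture(fixture_spec(n_templates = 60L), seed = 23)
  rd <- read_sam_blocks(fx$sam)
  lines <- unlist(lapply(rd$blocks, function(b) block_lines(split_lines(b))))
  x <- db_of(lines, header = rd$header)
  all_keys <- unlist(lapply(seq_len(db_count(x$db)), function(i) {
    k <- duplicate_key(x$db$infos[[i]])
    if (is.null(k)) NULL else k$owning
  }))
  for (n in c(1L, 3L, 8L)) {
    regions <- segment_regions(x$db, n)
    expect_lte(length(regions), n)
    # disjoint and covering: each owning key in exactly one region
    hits <- vapply(all_keys, function(k)
      sum(vapply(regions, function(r) k >= r$lo && k <= r$hi, TRUE)), 0)
    expect_true(all(hits == 1))
  }
  # all records at one position: a single nonempty range even for n = 4
  y <- db_of(replicate(3, sam_line(pos = 42L)))
  expect_length(segment_regions(y$db, 4L), 1L)
})
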