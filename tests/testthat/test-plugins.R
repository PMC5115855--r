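# Filters, duplicate keys and marking, compression backends.

test_that("an empty filter chain keeps everything; chains are conjunctions", {
  rec <- mk_rec()
  expect_true(apply_filters(rec, list()))
  keep_all <- function(r) TRUE
  drop_low_mapq <- function(r) r$mapq >= 30L
  drop_reverse <- function(r) bitwAnd(r$flag, 16L) == 0L
  recs <- list(mk_rec(mapq = 10L), mk_rec(flag = 16L), mk_rec(mapq = 60L))
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 1, 3))) {
    chain <- list(keep_all, drop_low_mapq, drop_reverse)[perm]
    got <- vapply(recs, apply_filters, TRUE, filters = chain)
    expect_identical(got, c(FALSE, FALSE, TRUE))  # invariant under reordering
  }
})

test_that("the region filter uses 1-based closed interval overlap", {
  h <- test_header()
  filt <- make_region_filter("chr1:1000-2000", h)
  # 0-based pos 999, 4M spans 1-based 1000..1003: overlap
  expect_true(filt(mk_rec(pos = 1000L, cigar = "4M")))
  # alignment entirely past 2000 (1-based 2001+): no overlap
  expect_false(filt(mk_rec(pos = 2001L, cigar = "4M")))
  # rightmost base exactly at region start
  expect_true(filt(mk_rec(pos = 997L, cigar = "4M")))
  expect_false(filt(mk_rec(pos = 996L, cigar = "4M")))
  # wrong reference and unmapped records drop
  expect_false(filt(mk_rec(rname = "chr2", pos = 1500L)))
  expect_false(filt(parse_sam_line("u\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", h)))
  expect_error(make_region_filter("chr1:2000-1000", h), "exceeds")
  expect_error(make_region_filter("chr1", h), "malformed")
})

info_for <- function(line, header = test_header(), gsn = 0L) {
  rec <- parse_sam_line(line, header, gsn = gsn)
  s <- record_store("memory")
  build_baminfo(rec, store_record(s, rec), header)
}

test_that("duplicate keys are canonical across mates and strand-sensitive", {
  q <- strrep("I", 4L)
  r1 <- info_for(paste0("p\t99\tchr1\t100\t60\t4M\t=\t300\t204\tACGT\t", q,
                        "\tMC:Z:4M"))
  r2 <- info_for(paste0("p\t147\tchr1\t300\t60\t4M\t=\t100\t-204\tACGT\t", q,
                        "\tMC:Z:4M"))
  k1 <- duplicate_key(r1); k2 <- duplicate_key(r2)
  expect_true(k1$paired && k2$paired)
  expect_identical(k1$key, k2$key)          # same key from either mate
  expect_identical(k1$owning, k2$owning)
  # FR vs RF at the same coordinates differ in the strand tuple
  rf1 <- info_for(paste0("q\t83\tchr1\t100\t60\t4M\t=\t300\t204\tACGT\t", q,
                         "\tMC:Z:4M"))
  expect_false(identical(duplicate_key(rf1)$key, k1$key))
  # single-end at the same position lives in a disjoint key space
  se <- info_for(sam_line(pos = 100L))
  expect_false(duplicate_key(se)$paired)
  expect_false(identical(duplicate_key(se)$key, k1$key))
  # ineligible kinds
  expect_null(duplicate_key(info_for(sam_line(flag = 0x100L))))
  expect_null(duplicate_key(info_for(sam_line(flag = 0x800L))))
  expect_null(duplicate_key(info_for("u\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")))
  # paired with unmapped mate degrades to an unpaired-key candidate
  half <- info_for(sam_line(flag = 0x1L + 0x8L, pos = 100L))
  expect_false(duplicate_key(half)$paired)
})

dupmark_db <- function(lines) {
  s <- record_store("memory")
  db <- alignment_db(with_unclipped = TRUE)
  h <- test_header()
  for (i in seq_along(lines)) {
    rec <- parse_sam_line(lines[i], h, gsn = i - 1L)
    db_insert(db, build_baminfo(rec, store_record(s, rec), h),
              qname = rec$qname)
  }
  resolve_mates(db)
  db
}

dup_flags <- function(db) {
  infos <- db$infos[seq_len(db_count(db))]
  stats::setNames(vapply(infos, function(i) i$duplicate, TRUE),
                  vapply(infos, function(i) i$gsn, 0L))
}

qual_of <- function(phreds) rawToChar(as.raw(phreds + 33L))

test_that("the highest-scoring single-end read survives; others are flagged", {
  lines <- c(
    sam_line(qname = "s1", pos = 500L, qual = qual_of(c(20, 15, 15, 0))),  # 50
    sam_line(qname = "s2", pos = 500L, qual = qual_of(c(20, 20, 30, 0))),  # 70
    sam_line(qname = "s3", pos = 500L, qual = qual_of(c(30, 30, 0, 0)))    # 60
  )
  db <- dupmark_db(lines)
  expect_identical(mark_duplicates(db), 2L)
  expect_identical(unname(dup_flags(db)), c(TRUE, FALSE, TRUE))
  # idempotent
  expect_identical(mark_duplicates(db), 0L)
})

test_that("tied pairs break to the lower min-gsn pair; both mates flagged", {
  q <- qual_of(rep(25, 4))
  pair <- function(name, p1, p2) c(
    paste0(name, "\t99\tchr1\t", p1, "\t60\t4M\t=\t", p2, "\t204\tACGT\t", q),
    paste0(name, "\t147\tchr1\t", p2, "\t60\t4M\t=\t", p1, "\t-204\tACGT\t", q)
  )
  db <- dupmark_db(c(pair("a", 100, 300), pair("b", 100, 300)))
  expect_identical(mark_duplicates(db), 2L)
  flags <- dup_flags(db)
  expect_identical(unname(flags), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("all-unique keys mark nothing", {
  lines <- vapply(1:20, function(i) sam_line(qname = paste0("u", i),
                                             pos = 100L * i), "")
  db <- dupmark_db(lines)
  expect_identical(mark_duplicates(db), 0L)
  expect_false(any(dup_flags(db)))
})

test_that("exactly one unflagged member per group; totals add up", {
  set.seed(31)
  fx <- generate_fixture(fixture_spec(n_templates = 80L), seed = 31)
  rd <- read_sam_blocks(fx$sam)
  lines <- unlist(lapply(rd$blocks, function(b) block_lines(split_lines(b))))
  s <- record_store("memory")
  db <- alignment_db(with_unclipped = TRUE)
  for (i in seq_along(lines)) {
    rec <- parse_sam_line(lines[i], rd$header, gsn = i - 1L)
    db_insert(db, build_baminfo(rec, store_record(s, rec), rd$header),
              qname = rec$qname)
  }
  resolve_mates(db)
  n_marked <- mark_duplicates(db)
  infos <- db$infos[seq_len(db_count(db))]
  keys <- vapply(infos, function(i) {
    k <- duplicate_key(i); if (is.null(k)) NA_character_ else k$key
  }, "")
  flags <- vapply(infos, function(i) i$duplicate, TRUE)
  for (k in unique(keys[!is.na(keys)])) {
    members <- which(keys == k & !is.na(keys))
    if (startsWith(k, "P")) {
      pairs <- length(members) / 2
      expect_identical(sum(!flags[members]), 2L)        # one pair unflagged
      expect_identical(sum(flags[members]), as.integer(2 * (pairs - 1)))
    } else {
      expect_identical(sum(!flags[members]), 1L)
      expect_identical(sum(flags[members]), length(members) - 1L)
    }
  }
  expect_identical(n_marked, sum(flags))
})

test_that("marking a stale or foreign region is a usage error", {
  db <- dupmark_db(sam_line())
  regions <- segment_regions(db, 2L)
  segment_regions(db, 3L)   # invalidates the previous segmentation
  expect_error(mark_duplicates(db, regions[[1]]), "segment_regions")
  expect_error(mark_duplicates(db, "not-a-region"), "segment_regions")
})

test_that("compression backends are interchangeable and failures fall back", {
  payload <- charToRaw(strrep("pipebam payload ", 100))
  member <- bgzf_compress_block(payload, backend = pipebam:::rdeflate_backend)
  expect_identical(bgzf_decompress(member), payload)
  broken <- function(p, level) stop("accelerator offline")
  expect_warning(member2 <- bgzf_compress_block(payload, backend = broken),
                 "falling back")
  expect_identical(bgzf_decompress(member2), payload)
})

test_that("50/50 backend routing decodes identically to a single backend", {
  set.seed(41)
  lines <- vapply(1:300, random_sam_line, "")
  path <- write_sam(lines)
  one <- tempfile(fileext = ".bam"); two <- tempfile(fileext = ".bam")
  run_pipeline(pipeline_config(path, one, backend = "zlib"))
  run_pipeline(pipeline_config(path, two, backend = c("zlib", "rdeflate")))
  r1 <- bam_records_of(one)
  r2 <- bam_records_of(two)
  expect_identical(r1, r2)
})
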