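# Block reading with line-boundary adjustment and line splitting.

test_that("small files and aligned boundaries produce the expected blocks", {
  # file smaller than one block
  lines <- c(sam_line(qname = "a"), sam_line(qname = "b"), sam_line(qname = "c"))
  path <- write_sam(lines)
  rd <- read_sam_blocks(path, block_size = 65536L)
  expect_length(rd$blocks, 1L)
  expect_identical(rd$blocks[[1]]$block_number, 0L)
  expect_identical(rawToChar(rd$blocks[[1]]$payload),
                   paste0(paste(lines, collapse = "\n"), "\n"))

  # byte at block_size - 1 is a newline: exact block, no carry
  body <- paste0(strrep("x\t", 10), "end")     # not SAM, exercise raw path
  path2 <- tempfile()
  writeLines(c("line-one", "ln2"), path2)      # "line-one\nln2\n": 9 + 4 bytes
  rd2 <- read_sam_blocks(path2, block_size = 9L)
  expect_length(rd2$blocks, 2L)
  expect_identical(length(rd2$blocks[[1]]$payload), 9L)
})

test_that("backward newline scan carries a partial line to the next block", {
  # two lines of 40 bytes each (incl. newline the lines are 41): block_size 50
  l1 <- strrep("a", 40); l2 <- strrep("b", 40)
  path <- tempfile()
  writeLines(c(l1, l2), path)
  rd <- read_sam_blocks(path, block_size = 50L)
  expect_length(rd$blocks, 2L)
  expect_identical(length(rd$blocks[[1]]$payload), 41L)
  expect_identical(rawToChar(rd$blocks[[2]]$payload), paste0(l2, "\n"))
  expect_identical(vapply(rd$blocks, function(b) b$block_number, 0L), 0:1)
})

test_that("a line longer than the block size is an explicit error", {
  path <- tempfile()
  writeLines(c(strrep("z", 100), "short"), path)
  expect_error(read_sam_blocks(path, block_size = 50L), "line exceeds block size")
})

test_that("split_lines enumerates line starts and matches a naive reader", {
  blk <- list(block_number = 0L, payload = charToRaw("a\nbb\nccc\n"),
              line_offsets = NULL)
  expect_identical(split_lines(blk)$line_offsets, c(0L, 2L, 5L))
  blk0 <- list(block_number = 0L, payload = raw(0), line_offsets = NULL)
  expect_identical(split_lines(blk0)$line_offsets, integer(0))

  # 1000 random newline-terminated lines against readLines
  set.seed(42)
  lines <- replicate(1000, paste(sample(letters, sample(1:30, 1), TRUE),
                                 collapse = ""))
  path <- tempfile()
  writeLines(lines, path)
  rd <- read_sam_blocks(path, block_size = 512L)
  got <- unlist(lapply(rd$blocks, function(b) block_lines(split_lines(b))))
  expect_identical(got, readLines(path))
  # offsets count equals newline count per block
  for (b in lapply(rd$blocks, split_lines)) {
    expect_identical(length(b$line_offsets), sum(b$payload == as.raw(10L)))
    expect_true(all(diff(b$line_offsets) > 0L))
  }
})

test_that("lossless partition holds for any block size >= max line length", {
  set.seed(11)
  lines <- replicate(200, paste(sample(letters, sample(1:40, 1), TRUE),
                                collapse = ""))
  path <- tempfile()
  writeLines(lines, path)
  for (bs in c(41L, 64L, 100L, 4096L)) {
    rd <- read_sam_blocks(path, block_size = bs)
    # concatenating payloads in block order reproduces the file body
    expect_identical(do.call(c, lapply(rd$blocks, `[[`, "payload")),
                     readBin(path, "raw", file.size(path)))
    got <- unlist(lapply(rd$blocks, function(b) block_lines(split_lines(b))))
    expect_identical(got, lines)
  }
})

test_that("header lines are consumed eagerly and parsed once", {
  path <- write_sam(c(sam_line(qname = "a"), sam_line(qname = "b")))
  rd <- read_sam_blocks(path)
  expect_s3_class(rd$header, "sam_header")
  expect_identical(rd$header$sequences$name, c("chr1", "chr2"))
  expect_identical(rd$header$read_groups$library, c("libA", "libB"))
  expect_identical(rd$header$read_groups$library_id, c(1L, 2L))
  # no '@' line inside any alignment block
  for (b in rd$blocks) expect_false(any(startsWith(block_lines(split_lines(b)), "@")))
})

test_that("gzip-compressed input, CRLF endings, and missing final newline work", {
  lines <- c(sam_line(qname = "a"), sam_line(qname = "b"))
  plain <- write_sam(lines)
  gz <- tempfile(fileext = ".sam.gz")
  con <- gzfile(gz, "wb")
  writeLines(readLines(plain), con)
  close(con)
  rd <- read_sam_blocks(gz)
  expect_identical(unlist(lapply(rd$blocks, function(b) block_lines(split_lines(b)))),
                   lines)

  crlf <- tempfile()
  writeBin(charToRaw(paste0(default_header_text(), lines[1], "\r\n", lines[2])),
           crlf)  # CRLF + unterminated final line
  rd2 <- read_sam_blocks(crlf)
  got <- unlist(lapply(rd2$blocks, function(b) block_lines(split_lines(b))))
  expect_identical(got, lines)
})

test_that("empty input yields an empty stream", {
  path <- tempfile()
  file.create(path)
  rd <- read_sam_blocks(path)
  expect_length(rd$blocks, 0L)
  expect_identical(nrow(rd$header$sequences), 0L)
})
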