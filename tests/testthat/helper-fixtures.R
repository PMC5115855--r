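# Small construction helpers used across the suite.

default_header_text <- function() {
  paste0("@HD\tVN:1.6\tSO:unknown\n",
         "@SQ\tSN:chr1\tLN:100000\n",
         "@SQ\tSN:chr2\tLN:100000\n",
         "@RG\tID:rg1\tLB:libA\tSM:s1\n",
         "@RG\tID:rg2\tLB:libB\tSM:s1\n")
}

test_header <- function() parse_sam_header(default_header_text())

# Write a SAM file from alignment lines (header prepended).
write_sam <- function(lines, path = tempfile(fileext = ".sam"),
                      header = default_header_text()) {
  writeLines(c(sub("\n$", "", strsplit(header, "\n")[[1]]), lines), path)
  path
}

# Compose a SAM alignment line from named fields with sensible defaults.
sam_line <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 100L,
                     mapq = 60L, cigar = "4M", rnext = "*", pnext = 0L,
                     tlen = 0L, seq = "ACGT", qual = "IIII", tags = character(0)) {
  paste(c(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual,
          tags), collapse = "\t")
}

# A parsed record with the same defaults.
mk_rec <- function(..., gsn = 0L, header = test_header()) {
  parse_sam_line(sam_line(...), header, gsn = gsn)
}

# Random canonical alignment line generator for property-style tests.
random_sam_line <- function(i) {
  L <- sample(20:60, 1)
  lead <- sample(0:5, 1); trail <- sample(0:5, 1)
  mid <- L - lead - trail
  cigar <- paste0(if (lead) paste0(lead, "S"), mid, "M",
                  if (trail) paste0(trail, "S"))
  sam_line(
    qname = sprintf("q%04d", i),
    flag = sample(c(0L, 16L), 1),
    rname = sample(c("chr1", "chr2"), 1),
    pos = sample(1:90000, 1),
    mapq = sample(0:60, 1),
    cigar = cigar,
    seq = paste(sample(c("A", "C", "G", "T", "N"), L, TRUE), collapse = ""),
    qual = rawToChar(as.raw(sample(33:73, L, TRUE))),
    tags = c(sprintf("NM:i:%d", sample(0:5, 1)), "RG:Z:rg1")
  )
}
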