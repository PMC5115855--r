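# Independent brute-force oracles.  These re-derive expectations directly
# from SAM text with their own field arithmetic, sharing no code with the
# package internals, so agreement is evidence rather than tautology.

# CIGAR walk via explicit tokenization (deliberately different style from
# the package's regex splitter).
oracle_cigar_walk <- function(cigar) {
  if (cigar == "*") return(list(lead = 0L, trail = 0L, ref_len = 0L))
  lens <- integer(0); kinds <- character(0)
  num <- ""
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch >= "0" && ch <= "9") num <- paste0(num, ch)
    else { lens <- c(lens, as.integer(num)); kinds <- c(kinds, ch); num <- "" }
  }
  lead <- 0L
  for (k in seq_along(kinds)) {
    if (kinds[k] == "S" || kinds[k] == "H") lead <- lead + lens[k] else break
  }
  trail <- 0L
  for (k in rev(seq_along(kinds))) {
    if (kinds[k] == "S" || kinds[k] == "H") trail <- trail + lens[k] else break
  }
  ref_len <- 0L
  for (k in seq_along(kinds)) {
    if (kinds[k] %in% c("M", "D", "N", "=", "X")) ref_len <- ref_len + lens[k]
  }
  list(lead = lead, trail = trail, ref_len = ref_len)
}

oracle_unclipped5 <- function(cigar, pos0, reverse) {
  w <- oracle_cigar_walk(cigar)
  if (reverse) pos0 + w$ref_len - 1L + w$trail else pos0 - w$lead
}

oracle_score <- function(qual_text, min_q = 15L) {
  if (qual_text == "*") return(0L)
  q <- utf8ToInt(qual_text) - 33L
  sum(q[q >= min_q])
}

# Parse the alignment lines of a SAM file into a plain data frame of text
# fields (the oracle's own reader).
oracle_read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    qname = vapply(fields, `[`, "", 1),
    flag = as.integer(vapply(fields, `[`, "", 2)),
    rname = vapply(fields, `[`, "", 3),
    pos0 = as.integer(vapply(fields, `[`, "", 4)) - 1L,
    cigar = vapply(fields, `[`, "", 6),
    qual = vapply(fields, `[`, "", 11),
    rg = vapply(fields, function(f) {
      hit <- grep("^RG:Z:", f[-(1:11)], value = TRUE)
      if (length(hit)) substring(hit[1], 6L) else ""
    }, ""),
    stringsAsFactors = FALSE
  )
}

# Brute-force Picard-style duplicate marking over a SAM file: group by
# (library, unclipped 5' fragment coordinates, strands), keep the
# highest-scoring member (pairs score as the sum of both ends; ties to the
# earliest record), flag the rest.  Returns a logical vector per record in
# file order.
oracle_mark_duplicates <- function(path, header_text = default_header_text()) {
  df <- oracle_read_sam(path)
  n <- nrow(df)
  rg_lines <- grep("^@RG", strsplit(header_text, "\n")[[1]], value = TRUE)
  rg_id <- sub(".*\tID:([^\t]+).*", "\\1", rg_lines)
  rg_lb <- sub(".*\tLB:([^\t]+).*", "\\1", rg_lines)
  lib <- ifelse(df$rg %in% rg_id, rg_lb[match(df$rg, rg_id)], "default")

  eligible <- bitwAnd(df$flag, 0x4L) == 0L & bitwAnd(df$flag, 0x100L) == 0L &
    bitwAnd(df$flag, 0x800L) == 0L & df$rname != "*"
  rev <- bitwAnd(df$flag, 0x10L) != 0L
  u5 <- rep(NA_integer_, n)
  score <- rep(0L, n)
  for (i in which(eligible)) {
    u5[i] <- oracle_unclipped5(df$cigar[i], df$pos0[i], rev[i])
    score[i] <- oracle_score(df$qual[i])
  }
  paired <- eligible & bitwAnd(df$flag, 0x1L) != 0L & bitwAnd(df$flag, 0x8L) == 0L
  mate <- rep(NA_integer_, n)
  for (idx in split(which(paired), df$qname[paired])) {
    if (length(idx) == 2L) { mate[idx[1]] <- idx[2]; mate[idx[2]] <- idx[1] }
  }
  key <- rep(NA_character_, n)
  for (i in which(eligible)) {
    s <- as.integer(rev[i])
    if (paired[i] && !is.na(mate[i])) {
      j <- mate[i]
      ends <- list(c(df$rname[i], u5[i], s), c(df$rname[j], u5[j], as.integer(rev[j])))
      o <- order(c(ends[[1]][1], ends[[2]][1]),
                 as.integer(c(ends[[1]][2], ends[[2]][2])),
                 as.integer(c(ends[[1]][3], ends[[2]][3])))
      ends <- ends[o]
      key[i] <- paste("P", lib[i], paste(ends[[1]], collapse = ","),
                      paste(ends[[2]], collapse = ","), sep = "#")
    } else {
      key[i] <- paste("U", lib[i], df$rname[i], u5[i], s, sep = "#")
    }
  }
  dup <- rep(FALSE, n)
  for (k in unique(key[!is.na(key)])) {
    members <- which(!is.na(key) & key == k)
    if (startsWith(k, "P")) {
      unit <- vapply(members, function(i) min(i, mate[i]), 0L)
      units <- split(members, unit)
      if (length(units) < 2L) next
      uscore <- vapply(units, function(u) score[u[1]] + score[mate[u[1]]], 0L)
      umin <- as.integer(names(units))
      best <- which(uscore == max(uscore))
      best <- best[which.min(umin[best])]
      for (j in seq_along(units)) if (j != best) dup[units[[j]]] <- TRUE
    } else {
      if (length(members) < 2L) next
      best <- members[score[members] == max(score[members])]
      dup[setdiff(members, min(best))] <- TRUE
    }
  }
  dup
}

# Duplicate flags of a BAM file in qname+flag-identified form, via the
# package's own BGZF/record decoders (used where samtools is unavailable).
bam_records_of <- function(path) {
  raw <- bgzf_decompress(path)
  stopifnot(identical(raw[1:4], c(charToRaw("BAM"), as.raw(1L))))
  l_text <- readBin(raw[5:8], "integer", size = 4, endian = "little")
  at <- 9L + l_text
  n_ref <- readBin(raw[at:(at + 3L)], "integer", size = 4, endian = "little")
  at <- at + 4L
  for (i in seq_len(n_ref)) {
    l_name <- readBin(raw[at:(at + 3L)], "integer", size = 4, endian = "little")
    at <- at + 4L + l_name + 4L
  }
  recs <- list()
  while (at <= length(raw)) {
    bs <- readBin(raw[at:(at + 3L)], "integer", size = 4, endian = "little")
    recs[[length(recs) + 1L]] <- decode_bam_record(raw[at:(at + 3L + bs)])
    at <- at + 4L + bs
  }
  recs
}
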