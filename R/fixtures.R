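# Synthetic SAM generator.  Produces well-formed SAM files with known
# template structure — paired and single-end reads, planted PCR-duplicate
# sets whose members keep identical unclipped 5' fragment coordinates while
# soft clips shift their clipped positions, both strands, MC tags on a
# configurable fraction, secondary/supplementary/unmapped records — plus a
# machine-readable ground-truth table of expected duplicate flags.  The
# truth table is computed by a brute-force pass with its own CIGAR walker
# and quality scorer, deliberately independent of the production code in
# the rest of the package.

#' Specification for a synthetic SAM fixture
#'
#' Defaults describe a small short-read library: 100 bp reads on two
#' references, ~300 bp inserts, 70% paired templates, duplicate-set sizes
#' drawn from a geometric distribution truncated at 6, soft clips of 1-5 bp
#' planted with probability 0.3 per read end, two read groups in distinct
#' libraries, and small fractions of secondary, supplementary and unmapped
#' records.
#'
#' @param n_templates Number of distinct DNA templates (duplicate sets).
#' @param paired_fraction Fraction of templates that are read pairs.
#' @param dup_geom_p Geometric parameter for set sizes (`1 + rgeom(p)`,
#'   truncated at `max_set_size`).
#' @param max_set_size Largest planted duplicate-set size.
#' @param clip_prob Probability of planting a soft clip at each read end.
#' @param clip_len Inclusive range of planted clip lengths.
#' @param rf_fraction Fraction of pairs with non-FR orientation (exercises
#'   cross-strand keys).
#' @param n_references,ref_length Reference dictionary.
#' @param read_length,insert_size Read length and insert-size range (bp).
#' @param qual_range Per-base phred quality range.
#' @param frac_secondary,frac_supplementary,frac_unmapped Extra-record
#'   fractions (relative to `n_templates`).
#' @param mc_fraction Fraction of pairs carrying MC (mate CIGAR) tags, so
#'   both mate-resolution paths are exercised.
#' @param n_read_groups Read groups, each its own library.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_templates = 400L, paired_fraction = 0.7,
                         dup_geom_p = 0.5, max_set_size = 6L,
                         clip_prob = 0.3, clip_len = c(1L, 5L),
                         rf_fraction = 0.1,
                         n_references = 2L, ref_length = 100000L,
                         read_length = 100L, insert_size = c(250L, 400L),
                         qual_range = c(2L, 40L),
                         frac_secondary = 0.04, frac_supplementary = 0.03,
                         frac_unmapped = 0.04, mc_fraction = 0.5,
                         n_read_groups = 2L) {
  spec <- structure(as.list(environment()), class = "fixture_spec")
  if (read_length > ref_length)
    stop("infeasible spec: read length exceeds reference length")
  if (insert_size[1] < read_length)
    stop("infeasible spec: insert size smaller than read length")
  if (max_set_size < 1L || n_templates < 1L)
    stop("infeasible spec: need at least one template and set size >= 1")
  spec
}

#' Generate a synthetic SAM fixture with its duplicate ground truth
#'
#' Same seed, same spec: byte-identical SAM file and truth table.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer RNG seed.
#' @param sam_path Output SAM path.
#' @param truth_path Optional path for the tab-separated truth table.
#' @return Invisibly, a list with `sam` (path), `truth` (data frame with
#'   one row per record: `qname`, `flag`, `order_index`, `dup_set_id`,
#'   `is_representative`, `expect_duplicate`) and `n_records`.
#' @export
generate_fixture <- function(spec, seed, sam_path = tempfile(fileext = ".sam"),
                             truth_path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  refs <- paste0("ref", seq_len(spec$n_references))
  rgs <- paste0("rg", seq_len(spec$n_read_groups))
  libs <- paste0("lib", seq_len(spec$n_read_groups))
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", refs, "\tLN:", spec$ref_length),
    paste0("@RG\tID:", rgs, "\tLB:", libs, "\tSM:sample1")
  )

  L <- spec$read_length
  rows <- list()
  emit <- function(qname, flag, rname, pos0, mapq, cigar, rnext, pnext0,
                   tlen, seq, qual, tags = character(0)) {
    rows[[length(rows) + 1L]] <<- list(
      qname = qname, flag = flag, rname = rname, pos0 = pos0, mapq = mapq,
      cigar = cigar, rnext = rnext, pnext0 = pnext0, tlen = tlen,
      seq = seq, qual = qual, tags = paste(tags, collapse = "\t")
    )
  }
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  rand_qual <- function(n) sample(spec$qual_range[1]:spec$qual_range[2], n, TRUE)
  qual_str <- function(q) rawToChar(as.raw(q + 33L))
  # clipped CIGAR preserving both unclipped ends: lead/trail soft clips eat
  # into the matched span, and POS moves right by the leading clip.
  clipped_cigar <- function(lead, trail) {
    mid <- L - lead - trail
    paste0(if (lead > 0L) paste0(lead, "S"), mid, "M",
           if (trail > 0L) paste0(trail, "S"))
  }
  draw_clip <- function() {
    if (stats::runif(1) < spec$clip_prob)
      sample(spec$clip_len[1]:spec$clip_len[2], 1L) else 0L
  }

  for (t in seq_len(spec$n_templates)) {
    set_size <- min(1L + stats::rgeom(1L, spec$dup_geom_p), spec$max_set_size)
    paired <- stats::runif(1) < spec$paired_fraction
    ref <- sample(refs, 1L)
    rg <- sample(seq_len(spec$n_read_groups), 1L)
    mapq <- sample(20:60, 1L)
    if (paired) {
      isize <- sample(spec$insert_size[1]:spec$insert_size[2], 1L)
      fstart <- sample(20L:(spec$ref_length - isize - 20L), 1L)
      fend <- fstart + isize - 1L
      # physical-end strands; FR unless this template exercises RF/FF
      strands <- if (stats::runif(1) < spec$rf_fraction)
        sample(list(c(TRUE, FALSE), c(FALSE, FALSE), c(TRUE, TRUE)), 1L)[[1]]
      else c(FALSE, TRUE)
      use_mc <- stats::runif(1) < spec$mc_fraction
      r1_is_first_end <- stats::runif(1) < 0.5
      for (ci in seq_len(set_size)) {
        qname <- sprintf("T%05d.C%d", t, ci)
        ends <- list()
        for (e in 1:2) {
          rev <- strands[e]
          # unclipped span of this physical end
          us <- if (e == 1L) fstart else fend - L + 1L
          lead <- draw_clip(); trail <- draw_clip()
          if (lead + trail >= L) { lead <- 0L; trail <- 0L }
          ends[[e]] <- list(rev = rev, ustart = us, pos = us + lead,
                            cigar = clipped_cigar(lead, trail),
                            end = us + L - 1L - trail)
        }
        lo <- min(ends[[1]]$pos, ends[[2]]$pos)
        hi <- max(ends[[1]]$end, ends[[2]]$end)
        tl <- hi - lo + 1L
        for (e in 1:2) {
          this <- ends[[e]]; other <- ends[[3L - e]]
          is_read1 <- (e == 1L) == r1_is_first_end
          flag <- 0x1L + 0x2L +
            (if (this$rev) 0x10L else 0L) + (if (other$rev) 0x20L else 0L) +
            (if (is_read1) 0x40L else 0x80L)
          tlen <- if (this$pos < other$pos ||
                      (this$pos == other$pos && is_read1)) tl else -tl
          tags <- c(paste0("RG:Z:", rgs[rg]),
                    if (use_mc) paste0("MC:Z:", other$cigar),
                    paste0("NM:i:", sample(0:3, 1L)))
          emit(qname, flag, ref, this$pos, mapq, this$cigar, "=", other$pos,
               tlen, rand_seq(L), qual_str(rand_qual(L)), tags)
        }
      }
    } else {
      rev <- stats::runif(1) >= 0.5
      ustart <- sample(20L:(spec$ref_length - L - 20L), 1L)
      for (ci in seq_len(set_size)) {
        qname <- sprintf("T%05d.C%d", t, ci)
        lead <- draw_clip(); trail <- draw_clip()
        if (lead + trail >= L) { lead <- 0L; trail <- 0L }
        flag <- if (rev) 0x10L else 0L
        emit(qname, flag, ref, ustart + lead, mapq, clipped_cigar(lead, trail),
             "*", -1L, 0L, rand_seq(L), qual_str(rand_qual(L)),
             paste0("RG:Z:", rgs[rg]))
      }
    }
  }

  n_extra <- function(frac) as.integer(round(frac * spec$n_templates))
  for (i in seq_len(n_extra(spec$frac_secondary))) {
    ref <- sample(refs, 1L)
    pos <- sample(20L:(spec$ref_length - L - 20L), 1L)
    emit(sprintf("SEC%04d", i), 0x100L, ref, pos, 0L, paste0(L, "M"),
         "*", -1L, 0L, rand_seq(L), qual_str(rand_qual(L)),
         paste0("RG:Z:", rgs[1]))
  }
  for (i in seq_len(n_extra(spec$frac_supplementary))) {
    ref <- sample(refs, 1L)
    pos <- sample(20L:(spec$ref_length - L - 20L), 1L)
    half <- L %/% 2L
    emit(sprintf("SUP%04d", i), 0x800L, ref, pos, 30L,
         paste0(half, "M", L - half, "H"), "*", -1L, 0L,
         rand_seq(half), qual_str(rand_qual(half)),
         paste0("RG:Z:", rgs[1]))
  }
  for (i in seq_len(n_extra(spec$frac_unmapped))) {
    emit(sprintf("UNM%04d", i), 0x4L, "*", -1L, 0L, "*", "*", -1L, 0L,
         rand_seq(L), qual_str(rand_qual(L)), paste0("RG:Z:", rgs[1]))
  }

  rows <- rows[sample(length(rows))]   # unsorted emission order
  lines <- vapply(rows, function(r) {
    paste(c(r$qname, r$flag, r$rname, r$pos0 + 1L, r$mapq, r$cigar, r$rnext,
            r$pnext0 + 1L, r$tlen, r$seq, r$qual,
            if (nzchar(r$tags)) r$tags), collapse = "\t")
  }, "")
  writeLines(c(header, lines), sam_path)

  truth <- fixture_truth(rows, rgs, libs)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(sam = sam_path, truth = truth, n_records = length(rows)))
}

# --- independent ground-truth pass ------------------------------------------
# Everything below re-derives duplicate expectations from the emitted text
# fields with its own CIGAR arithmetic and scorer.

truth_clips <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  lead <- 0L
  for (i in seq_along(kinds)) {
    if (kinds[i] %in% c("S", "H")) lead <- lead + lens[i] else break
  }
  trail <- 0L
  for (i in rev(seq_along(kinds))) {
    if (kinds[i] %in% c("S", "H")) trail <- trail + lens[i] else break
  }
  ref_len <- sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
  list(lead = lead, trail = trail, ref_len = ref_len)
}

truth_unclipped5 <- function(cigar, pos0, reverse) {
  cl <- truth_clips(cigar)
  if (reverse) pos0 + cl$ref_len - 1L + cl$trail else pos0 - cl$lead
}

truth_score <- function(qual_text, min_q = 15L) {
  q <- as.integer(charToRaw(qual_text)) - 33L
  sum(q[q >= min_q])
}

fixture_truth <- function(rows, rgs, libs) {
  n <- length(rows)
  flag <- vapply(rows, function(r) r$flag, 0L)
  qname <- vapply(rows, function(r) r$qname, "")
  df <- data.frame(
    qname = qname, flag = flag, order_index = seq_len(n) - 1L,
    dup_set_id = NA_integer_, is_representative = FALSE,
    expect_duplicate = FALSE, stringsAsFactors = FALSE
  )
  eligible <- bitwAnd(flag, 0x904L) == 0L &
    vapply(rows, function(r) r$rname != "*", TRUE)
  lib_of <- function(r) {
    m <- regmatches(r$tags, regexec("RG:Z:([^\t]+)", r$tags))[[1]]
    if (length(m)) libs[match(m[2], rgs)] else "lib0"
  }
  u5 <- rep(NA_integer_, n)
  score <- rep(0L, n)
  for (i in which(eligible)) {
    r <- rows[[i]]
    u5[i] <- truth_unclipped5(r$cigar, r$pos0, bitwAnd(r$flag, 0x10L) != 0L)
    score[i] <- truth_score(r$qual)
  }
  paired <- eligible & bitwAnd(flag, 0x1L) != 0L & bitwAnd(flag, 0x8L) == 0L
  # pair up primary paired ends by read name
  mate_of <- rep(NA_integer_, n)
  by_name <- split(which(paired), qname[paired])
  for (idx in by_name) {
    if (length(idx) == 2L) {
      mate_of[idx[1]] <- idx[2]
      mate_of[idx[2]] <- idx[1]
    }
  }
  key <- rep(NA_character_, n)
  for (i in which(eligible)) {
    r <- rows[[i]]
    s <- as.integer(bitwAnd(r$flag, 0x10L) != 0L)
    if (paired[i] && !is.na(mate_of[i])) {
      j <- mate_of[i]
      m <- rows[[j]]
      e1 <- c(r$rname, u5[i], s)
      e2 <- c(m$rname, u5[j], as.integer(bitwAnd(m$flag, 0x10L) != 0L))
      ord <- order(c(e1[1], e2[1]), as.integer(c(e1[2], e2[2])),
                   as.integer(c(e1[3], e2[3])))
      ends <- list(e1, e2)[ord]
      key[i] <- paste("P", lib_of(r), paste(ends[[1]], collapse = ","),
                      paste(ends[[2]], collapse = ","), sep = "|")
    } else {
      key[i] <- paste("U", lib_of(r), r$rname, u5[i], s, sep = "|")
    }
  }
  set_id <- 0L
  for (k in unique(key[!is.na(key)])) {
    members <- which(!is.na(key) & key == k)
    is_pairkey <- startsWith(k, "P")
    if (is_pairkey) {
      unit_id <- vapply(members, function(i) min(i, mate_of[i]), 0L)
      units <- split(members, unit_id)
      if (length(units) < 2L) next
      set_id <- set_id + 1L
      uscore <- vapply(units, function(u)
        score[u[1]] + score[mate_of[u[1]]], 0L)
      umin <- as.integer(names(units))
      best <- which(uscore == max(uscore))
      best <- best[which.min(umin[best])]
      for (j in seq_along(units)) {
        for (i in units[[j]]) {
          df$dup_set_id[i] <- set_id
          df$is_representative[i] <- j == best
          df$expect_duplicate[i] <- j != best
        }
      }
    } else {
      if (length(members) < 2L) next
      set_id <- set_id + 1L
      best <- members[score[members] == max(score[members])]
      best <- min(best)
      for (i in members) {
        df$dup_set_id[i] <- set_id
        df$is_representative[i] <- i == best
        df$expect_duplicate[i] <- i != best
      }
    }
  }
  df
}
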