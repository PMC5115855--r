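---
title: "Design of the pipebam conversion pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of the pipebam conversion pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipebam)
```

# The pipeline model

`pipebam` converts SAM text to coordinate-sorted, duplicate-marked,
BGZF-compressed BAM in a single pass over the input. The design splits the
conversion into stages connected as a data pipeline — block reading,
line splitting, SAM parsing, record virtualization, alignment-database
construction, analyzer execution, block compression and writing — where
each stage operates on independent units (data blocks, records, position
regions, BAM blocks). Stages that define a global order — boundary
adjustment, the block dispatcher, the final writer — are single-consumer
by construction; every other stage is an ordered map over its units and
can therefore run its units concurrently without changing any output
byte. That property (order defined by unit index, never by completion
time) is what the test suite pins down as worker-count determinism.

Two invariants carry the whole design:

* **Block independence.** Read blocks end at SAM line boundaries (the
  reader scans each raw block backwards to its last newline and carries
  the tail into the next block), so no line ever spans two blocks and a
  block can be parsed with no bytes from any other block.
* **Database order is output order.** The baminfo database arranges
  entries by (reference id, clipped position, global sequence number),
  with entries lacking any placement coordinate last. Ordered traversal
  *is* the coordinate sort; no sorting pass exists. An unmapped record
  whose RNAME/POS carry its mate's coordinate sorts at that coordinate,
  which is the convention of coordinate-sorted BAM.

The global sequence number (gsn) is assigned at parse time as the
record's ordinal of first appearance. It serves three roles: stable
ordering for records at equal coordinates, the duplicate tie-break, and
the definition of "input order" for streaming runs.

# Streaming versus pooled runs

Without analyzers, records flow from parsing through virtualization
straight to the dispatcher: stages 5 and 6 are skipped, input order is
preserved, the header keeps its sort-order tag, and only memory mode is
allowed — a streaming run holds just the in-flight window, so spilling
records to storage would buy nothing and cost a round trip, and the
configuration constructor rejects the combination up front.

With analyzers, all input pools in the record store and the database
before analysis starts, because duplicate marking (like any whole-file
analysis) cannot decide a group until the last member has been seen.

# Record virtualization

Encoded records live behind virtual addresses: a slot index in memory
mode, a byte offset into a spill file in storage mode. Both modes expose
the encoded byte *size* on the address itself, which lets the dispatcher
pack 64 KiB blocks without touching record bodies. Records are immutable
once stored; the duplicate flag is applied at write time by patching the
FLAG field of the fetched bytes (offset 14–15 past the record-length
prefix). That choice keeps memory and storage mode byte-identical — a
storage-mode store cannot cheaply rewrite the middle of its spill file —
and the mode-equivalence test compares whole output files by hash.

The spill layout is simply concatenated encoded records. It makes
addresses self-describing and reuses the one encoder; nothing external
ever reads the spill file, and it is deleted on normal close.

# The baminfo database

Each database entry holds only fixed-size derived fields: reference id,
clipped position, unclipped 5' coordinate, unclipped end, flag, mate
reference, mate unclipped 5', library id, the summarized quality score,
the virtual address, the gsn and the duplicate bit. No read name, CIGAR,
sequence, qualities or tags — anything an analyzer needs from those is
summarized into the entry at creation time.

Excluding read names creates a mate-resolution question: pair scores and
(absent an `MC` tag) mate coordinates need the partner record. The
resolution here is a transient side table mapping read name to entry
index, filled during insertion for primary paired records and dropped by
`resolve_mates()` once every pair has exchanged gsn, score and unclipped
coordinate. When the `MC` (mate CIGAR) tag is present the mate's
unclipped 5' is computed directly at entry creation instead; the fixture
generator emits `MC` on a configurable fraction of pairs precisely so
both paths stay exercised.

# Duplicate marking

Candidates are keyed by library and by the unclipped 5' coordinate and
strand of each fragment end. Both soft and hard clips are restored when
computing unclipped coordinates, negative coordinates are kept rather
than clamped, and `=`/`X` count as `M` throughout. Pair keys place their
two (reference, coordinate, strand) ends in lexicographic order so both
mates derive the same key; unpaired candidates — true single-end reads
and paired reads with unmapped mates — form a disjoint key space and are
never compared against pair ends. Secondary (0x100), supplementary
(0x800) and unmapped records are stored and written but never candidates
and never flagged.

The representative of a group is the member with the highest score: the
sum of phred base qualities at or above 15 (records without qualities
score zero), summed over both mates for pairs. Ties break to the lowest
gsn (lowest min-gsn for pairs). All non-representatives are flagged,
both mates of a losing pair together. The threshold 15 and the summed
pair score are the documented Picard-compatible choice; optical-duplicate
subclassification (pixel-distance parsing of read names) is deliberately
out of scope, so every duplicate is flagged uniformly with 0x400.

Analyzer parallelism decomposes the *unclipped* key space: every
candidate group has a single owning coordinate (the canonical first
end's reference and unclipped 5'), `segment_regions()` partitions the
occupied owning coordinates into contiguous ranges, and a group can
therefore never straddle two regions. Marking region by region is
exactly equal to marking the whole database in one piece — the
acceptance suite asserts flag-for-flag equality for 1, 2, 7 and 16
segments.

# BAM and BGZF output

The record encoder implements the BAM binary layout bit-exactly:
little-endian fixed header, UCSC binning (`reg2bin`, bin 4680 for
unmapped), 28-bit CIGAR lengths, the 16-letter 4-bit nucleotide code,
0xff quality fill for missing qualities, and typed optional tags
(integer tags are serialized as int32 and surface as SAM type `i`,
matching how reference tools print them).

The dispatcher packs records greedily into manifests of at most 65536
uncompressed bytes; a single oversized record gets its own manifest and
spans consecutive BGZF members at serialization, which the BAM
specification permits. Each member is a gzip member with the `BC` extra
field (BSIZE = member length − 1), a raw deflate stream, CRC32 and
ISIZE; the file ends with the fixed 28-byte empty-member EOF marker. In
the corner case where an incompressible payload would push BSIZE past
its 16-bit bound, the payload is halved and emitted as two members.

Compression routes through a pluggable backend with the raw-deflate
contract (`function(payload, level) -> raw`). The default backend calls
zlib (level 6 by default — the zlib default — and configurable 0–9); an
alternate pure-R backend exists to exercise multi-backend routing, and a
failing backend falls back to the default for the affected block with a
warning. Blocks may be split round-robin across several backends — the
software analogue of offloading part of the stream to a hardware
deflate engine — and the output decodes identically however the split
falls, because every backend produces a valid deflate stream of the
same payload.

# The synthetic-data generator

`generate_fixture()` emulates a small short-read library: 100 bp reads
on two 100 kb references, 70% paired templates with 250–400 bp inserts,
duplicate-set sizes `1 + Geometric(0.5)` truncated at 6, soft clips of
1–5 bp planted at each read end with probability 0.3, two read groups
in distinct libraries, ~10% of pairs in non-FR orientation, `MC` tags
on half the pairs, and small fractions of secondary, supplementary and
unmapped records. Planted duplicates re-emit a template's fragment
coordinates under fresh names with resampled qualities and fresh clips;
the clips move the *clipped* position while the unclipped keys
coincide — exactly the situation that makes the unclipped arrangement
necessary. Emission order is shuffled so sorting is always exercised.

The ground-truth table is computed inside the generator by a brute-force
pass over the emitted text with its own CIGAR walker and quality scorer,
sharing no code with the pipeline; the test suite adds a third,
independent oracle implementation. What the generator does *not*
emulate: realistic base-error and quality profiles, chimeric
alignments, reference-sequence content (sequences are uniform random),
optical-duplicate pixel geometry, and malformed input. Passing tests
therefore demonstrate correctness of the conversion and marking logic
under well-formed inputs, not robustness to pathological real-world
files.

# Numerical and policy choices

* Coordinates are 0-based half-open internally; SAM text I/O converts
  to and from 1-based. Phred is ASCII − 33.
* Default read-block size 64 KiB; a single line longer than the block
  size is a hard error rather than silent truncation.
* Region filters use the 1-based closed CLI dialect and clipped
  alignment spans; unmapped records never overlap any region.
* Validation in the tests and acceptance script runs at desk scale:
  one ~10,000-record fixture for round-trip, mode, worker and BGZF
  properties, twenty ~400-record seeds for duplicate-marking
  equivalence, and a ~900-record fixture for segmentation invariance.

# Known limitations

Reading BAM (or writing CRAM) is out of scope, as are `.bai` indexes.
Parsing and encoding are pure R per record; throughput is adequate for
the package's analytical scale but the architecture, not the constant
factor, is what this implementation demonstrates. True OS-level
parallelism applies only to block compression (fork-based, POSIX
platforms); all other stages execute their ordered maps sequentially,
which the determinism contract renders observationally equivalent.
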