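# pipebam

Single-pass conversion of SAM alignment text into coordinate-sorted,
duplicate-marked, BGZF-compressed BAM, built as a staged pipeline with a
plug-in architecture for filters and analyzers.

## The problem

Short-read sequencing workflows spend a large share of their preprocessing
time between the aligner and the variant caller: parsing SAM text, sorting
alignments by coordinate, marking PCR/optical duplicate reads, and writing
compressed BAM. Conventional toolchains run these as separate passes, each
re-reading and re-writing the whole data set. `pipebam` implements the
alternative design: one pass through the input feeds a chain of stages —

1. **block reading** — the SAM file is read as ~64 KiB data blocks whose
   boundaries are moved back to the last newline, so every block is a
   self-contained set of SAM lines;
2. **line splitting** — each block is scanned for line start offsets;
3. **SAM parsing** — lines become binary alignment records (the BAM record
   layout), each carrying a *global sequence number* (gsn), its ordinal of
   first appearance in the file;
4. **record virtualization** — encoded records are placed in main memory
   (*memory mode*) or appended to a spill file (*storage mode*) behind
   uniform virtual addresses;
5. **alignment database** — each record contributes a compact *baminfo*
   entry (positions, flags, mate info, a summarized quality score, the
   virtual address — no long strings), arranged in reference-position
   space under the clipped position and, when duplicate marking is active,
   also under the unclipped 5' position;
6. **analyzers** — plug-ins run over the pooled database, in parallel over
   disjoint segments of the unclipped-position space;
7. **BAM writing** — a single-threaded dispatcher packs records into
   ≤ 64 KiB BAM blocks using only addresses and sizes, blocks are
   deflate-compressed independently (parallelizable, pluggable codec
   backends) and written in dispatch order with BGZF framing.

Sorted output falls out of an ordered traversal of the database — there is
no separate sorting step — and the duplicate flag (FLAG 0x400) is applied
at serialization time, so stored records stay immutable.

## Duplicate marking

The shipped `dupmark` analyzer follows the Picard MarkDuplicates criteria:
candidates are grouped by library and by the **unclipped 5' position** and
strand of each fragment end — the coordinate a read's 5' end would occupy
had no soft/hard clipping occurred, `pos − leading clips` on the forward
strand and `alignment end + trailing clips` on the reverse. Read pairs
(both ends mapped) form keys from both ends in canonical order, so the key
is identical from either mate; single-end reads, and paired reads whose
mate is unmapped, compete in a disjoint key space. Within each group the
member with the highest score — the sum of base qualities ≥ 15, summed
over both mates for pairs — is kept; ties break to the earliest record
(lowest gsn); every other member, both mates for pairs, is flagged.
Secondary, supplementary and unmapped records are never candidates, and
detection never crosses libraries.

## Worked example

```r
library(pipebam)

# a synthetic library with planted duplicate sets and ground truth
fx <- generate_fixture(fixture_spec(n_templates = 100), seed = 7,
                       sam_path = "readme.sam", truth_path = "readme.tsv")
sum(fx$truth$expect_duplicate)
#> [1] 189

s <- run_pipeline(pipeline_config("readme.sam", "readme.bam",
                                  analyzers = "dupmark"))
s
#> pipebam conversion summary
#>   records in:        368
#>   records filtered:  0
#>   records out:       368
#>   duplicates marked: 189
#>   BAM blocks:        2
#>   output:            readme.bam
```

The 368 records of the fixture (paired and single-end, soft-clipped, with
secondary/supplementary/unmapped stragglers) convert in one pass; the 189
marked duplicates equal the generator's truth table, and `samtools view -c
-f 1024 readme.bam` reports the same count. The output is
coordinate-sorted (`SO:coordinate`) with unmapped records last.

Shell front ends live in `inst/cli/`:

```sh
Rscript inst/cli/pipebam-fixture --seed 3 -o fx.sam --truth fx.tsv
Rscript inst/cli/pipebam convert fx.sam -o fx.bam \
    --analyzer dupmark --filter region=ref1:1-50000 --workers 2
```

## Scope

SAM in (plain or gzip), BAM out. No BAM reading, no CRAM, no `.bai`
indexing, no optical-duplicate subclassification, and no hardware
compression offload — though the codec backend interface accepts any
deflate-compatible implementation.
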