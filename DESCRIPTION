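Package: pipebam
Title: Staged High-Throughput SAM to BAM Conversion with Pluggable Filters and Analyzers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts SAM-format alignment text to coordinate-sorted,
    duplicate-marked, BGZF-compressed BAM in a single pass through a staged
    pipeline: block reading with line-boundary adjustment, line splitting,
    SAM parsing into binary alignment records carrying global sequence
    numbers, record virtualization into main memory or a spill file behind
    uniform virtual addresses, a compact position-indexed alignment database
    (with clipped and unclipped arrangements), plug-in filters and analyzers
    (a region-overlap filter and a Picard-compatible duplicate-marking
    analyzer ship with the package), and an order-preserving dispatcher that
    packs records into 64 KiB BAM blocks compressed through a pluggable
    deflate backend. Includes a deterministic synthetic-SAM generator with a
    machine-readable duplicate ground-truth table for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    jsonlite
SystemRequirements: zlib
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
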