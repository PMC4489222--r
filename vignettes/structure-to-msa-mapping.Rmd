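---
title: "Structure-to-MSA coordinate mapping: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-to-MSA coordinate mapping: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msamap)
```

## The coordinate model

`msamap` answers one question: *which columns of a curated multiple
sequence alignment correspond to a given stretch of residues in an RNA 3D
structure, and what sequence variants live there?* The difficulty is that
the two coordinate systems are connected only indirectly. Structure files
number residues by author convention — numbering can start anywhere and,
when a structure is deliberately numbered to match a homolog, insertion
codes appear (residue 190 is followed by 190A, 190B, …). Crystallized
constructs may also carry engineered sequence with no biological
counterpart, and may lack disordered stretches that biological sequences
have. MSA columns, finally, are padded with gaps that differ per sequence.

The package composes two maps, both anchored on a single reference (the
*lookup sequence*) that appears in both alignments:

* **Residue map** `r`: built from the pairwise *lookup alignment* of the
  structure sequence against the lookup sequence. Scanning columns left to
  right, each structure residue aligned to a lookup residue receives that
  residue's *natural position* — the running index 1…L over the ungapped
  lookup sequence. A structure residue over a lookup gap is *unmappable*
  (`NA`): it has no reference equivalent. We draw no distinction between
  engineered inserts and ordinary unalignable residues; both are simply
  positions where the reference has nothing aligned.
* **Column map** `c`: from the lookup sequence's own row in the *data
  alignment* (the MSA). Its p-th non-gap character sits in column `c(p)`.

Both maps are strictly increasing where defined, so residue order and
column order always agree. A query range `[i, j]` resolves to the closed
column interval `[c(r(i)), c(r(j))]`. Two consequences are deliberate:
interior columns where the lookup row is gapped (insertions carried by
*other* sequences) are included, because they are part of the addressed
region of the alignment; and interior unmappable residues are bridged,
because extraction is purely column-interval based — only *endpoints*
must be mappable. An unmappable endpoint fails validation with the error
condition "No data available in table".

All coordinates are 1-based closed intervals, the convention of both
sequence databases and structural biology.

## Query addressing and limits

Residues are addressed by Unit IDs, the pipe-delimited grammar
`pdb|model|chain|identity|number|atom|alt_id|insertion_code|symmetry`.
Comparisons for query purposes ignore the residue identity, atom and
alt-id fields; `pdb_id` and chain compare case-sensitively (PDB chains
are case-sensitive), insertion codes case-insensitively (conventions
drift between sources). Whitespace around delimiters is stripped for
copy/paste tolerance. Only closed inclusive ranges exist, so a lone
colon at the start or end of a range item is a syntax error, and the
model number is always required.

Query limits are configuration with defaults of **5 ranges** per query
and **50 residues** per range, counted in *structure residues* (polymer
indices), not alignment columns — limits phrased in nucleotides of the
query structure stay meaningful regardless of how gap-rich the alignment
is. Endpoint order is likewise judged in polymer order, i.e. the order of
the numbering table, so an insertion-code run 190 → 190A → … → 190L
validates correctly even though the numeric part never increases.
Overlapping or duplicate ranges are allowed and processed independently.

## Reporting conventions

The distinct-variant summary groups the per-sequence display strings
(gapped extracts, multiple ranges joined by `", "`). Percentages are
computed at full precision and rendered to two decimals; counts always
sum to the number of sequences, and rendered percentages sum to 100
within rounding (±0.005 per row). The default order — count descending,
then variant ascending — is our choice; a deterministic tie-break is
required for reproducible, byte-identical output, which also underpins
the guarantee that re-running a saved `units=` string against the same
registry reproduces the result exactly.

Two display flags mirror the usual green/blue highlighting: a row
`matches_structure` when its gap-stripped extract equals the structure's
own residues in every range, comparing only *mapped* residues (insert
residues have no columns, so a range bridging an insert compares its
biological flanks); `is_lookup` marks the anchor sequence. `T` and `U`
compare as equivalent throughout — reference databases store rRNA as DNA
— but residues are never rewritten on output. Filtering is literal,
case-insensitive substring matching over the displayed text (gaps count
as characters) and is display-level only: it never changes summary
counts.

Serialization: JSON and TSV carry the full unpaginated tables with
per-range structure; FASTA/Clustal exports concatenate the per-range
column blocks, since those formats cannot carry a separator. The JSON
field layout is self-defined and versioned (`schema_version`).

## File-format decisions

Gap characters `.` and `~` are accepted on input and normalized to `-`
(dialects vary between curation pipelines); normalization is idempotent.
Residues are uppercased on input. Clustal conservation lines are ignored
on input and a blank one is emitted per block on output so that
third-party readers expecting them stay compatible. The metadata join
key is the FASTA header's first token (`seq_id`), treated as an opaque
identifier. When no numbering sidecar is supplied, residues are numbered
sequentially 1…N — the common case for structures numbered from 1.

When checking that the lookup sequence agrees between the two alignments,
we compare only over the span present in the lookup alignment, locating
it in the data copy by exact substring match: reference database copies
are often longer at the 3' (or 5') end, which has no effect on mapping —
the match offset simply shifts natural numbering. An ambiguous
(multiple-site) match is an error rather than a guess.

## What the synthetic fixtures emulate

`simulate_data_alignment()` evolves `n` sequences from one ancestor
(which doubles as the lookup sequence) by independent per-position
substitutions and indels, *recorded at the alignment level*: a deletion
gaps one ancestor column; an insertion opens 1–3 new columns gapped in
every other sequence. Because every event is recorded as columns while
the alignment is built, the natural-position → column truth table is
exact by construction, not inferred by re-alignment.
`make_structure_variant()` then derives a structure chain from the lookup
sequence with a *missing span* (unresolved residues) and an *engineered
insert* that replaces part of the biological sequence, with gaps placed
exactly as a curator would place them, and optionally numbers the insert
as an insertion-code run. Defaults (20 sequences × 120 columns,
substitution rate 0.05, indel rate 0.02, RNA alphabet) are in the range
typical of a moderately diverged rRNA alignment block; tests also sweep
20–50 sequences × 100–300 columns.

The generator deliberately does **not** model covariation, secondary
structure, rate heterogeneity, or realistic rRNA phylogeny: its purpose
is exact coordinate ground truth, not evolutionary realism. Passing
tests therefore demonstrate that the *coordinate arithmetic and
reporting* are correct on alignments of realistic shape; they say
nothing about the biological quality of any particular curated
alignment, which the package consumes but does not construct. Likewise
the pairwise lookup alignment is an input — real ones are curated
manually with the 3D structure at hand — and the package validates but
never computes it.

## Problem sizes and verification

The oracle-equivalence suite runs 100 seeded fixtures with sizes drawn
from 20–50 sequences × 100–300 columns, each with an engineered insert
(3–10 nt) and a missing span (2–8 nt), alternating sequential and
insertion-code numbering; every structure residue's mapped column and
every extracted variant is compared against the generator's truth tables
by brute force (direct character indexing, independent of the mapping
code). Format round trips, map monotonicity, summary conservation and
interval-tiling properties are checked on further seeds, and the Clustal
writer is cross-checked against an independent parser. These sizes keep
the whole suite in the tens of seconds while covering every code path;
the mapping arithmetic is O(alignment length) and scales linearly to
full-length rRNA (thousands of columns) without further consideration.

## Known limitations

* One alignment per query: ranges cannot span molecules stored in
  separate alignments (SSU vs LSU vs 5S) — by design, mirroring how such
  alignments are curated and stored.
* Symmetry operators and atom-level fields of Unit IDs are carried and
  compared (symmetry only when both sides have one) but never expanded.
* Stockholm/NEXUS input, secondary-structure rendering, and live
  database links are out of scope.
* The registry is a declarative YAML file; no database backend or HTTP
  service is included.
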