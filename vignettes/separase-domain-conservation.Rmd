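---
title: "Conservation profiling and constrained motif scanning of an alpha-solenoid regulatory domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation profiling and constrained motif scanning of an alpha-solenoid regulatory domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepmotif)
```

## Scope and model

`sepmotif` implements the sequence-analysis workflow used to characterize
the N-terminal regulatory domain of separase: a multi-group conservation
profile over a precomputed multiple alignment, a scanner for a
context-constrained cysteine motif, a phyletic survey across clades, a
mapping of conserved positions onto structure coordinates with a
β-carbon contact criterion, and a check of conserved positions against a
missense-variant table. Alignment construction itself (e.g. with MAFFT)
is deliberately outside the package: the aligned FASTA is an *input*, and
all conclusions are conditional on it.

Every coordinate in the package is 1-based. Structure residue numbers
follow the structural-biology convention (C450 means "the cysteine at
residue 450"), and alignment columns are numbered 1..L. The two
coordinate systems are connected by `column_to_residue()` /
`residue_to_column()`, which are exact inverses on non-gap positions.

## Conservation semantics

For a column $c$ and a group $G$ of aligned sequences, the state is

* `gapped` if any member of $G$ has `-` at $c$ — identity is only called
  among aligned residues, so one deletion in a group suppresses the call
  rather than letting the remaining members vote;
* `identical(r)` if all members carry the same residue $r \neq$ `X`;
* `class_conserved(k)` if residues differ but all fall in one
  physicochemical class $k$;
* `unconserved` otherwise.

A column is **universal** when every group is `identical` and the residue
is the same across groups. This is intentionally stricter than
"identical within each group": a column that is all-C in nematodes and
all-S in vertebrates is group-diagnostic, not universal. Only identical
columns feed universality; class-conserved columns are reported but never
promoted.

The class table partitions the alphabet: negative {D, E}, positive
{K, R, H}, aromatic {F, W, Y}, aliphatic {I, L, V, M}, alcohol {S, T},
small {A, G, C, P}, and a remainder {N, Q, X}. The six named classes
match the coloring scheme conventionally used in per-group alignment
figures; the assignment of N and Q to the remainder (rather than, say, a
polar-amide class) is a design choice — the membership can be overridden
through the `class_table` argument wherever classification is used. The
unknown residue `X` never supports any conservation call, never matches a
motif literal, and never satisfies a context constraint: an ambiguous
residue should not manufacture evidence.

## The motif model

Patterns are literal/wildcard strings: `CxCxxC` places literal cysteines
at offsets 0, 2 and 5 and accepts anything at the other three positions.
This is deliberately not a full regular-expression or PROSITE engine —
the scientific object is a short exact motif, and a restricted language
keeps hits auditable.

A context constraint demands a residue inside an inclusive window
measured from the first pattern position. The offset convention follows
the H442/C448 pair: "4–6 residues upstream" means
$\mathrm{start} - i$ for $i \in \{4, 5, 6\}$, so H442 sits at offset
$448 - 442 = 6$ from C448. Windows are truncated at sequence boundaries.
Context evaluation always happens on ungapped residue coordinates;
alignment-level questions (does the motif occupy the same columns in
every row?) are answered separately by `motif_column_consistency()`.

All overlapping matches are reported. The observation that each
motif-bearing sequence carries exactly one `CxCxxC` is a *finding* the
survey verifies (`n_with_unique_motif`), not an assumption of the
scanner. The survey reports the context fraction under both candidate
denominators — motif-bearing sequences (`frac_context`, the default
reading) and all surveyed sequences (`frac_context_all`) — because a
"fraction of cases" is ambiguous between the two; users can quote either.

## Structure mapping

Residues queried against a structure model divide into resolved (Cα
present) and unresolved; unresolved positions are reported, never
silently dropped, because absence from a deposited model (e.g. a
disordered loop) is itself informative — in the motivating structure
neither the motif's first cysteine nor its upstream histidine was built.

Contacts use the β-carbon, the standard side-chain-direction proxy, with
a strict inequality at the threshold: $d(C\beta_i, C\beta_j) < 6$ Å. The
strictness matters only on a measure-zero boundary but is pinned by a
test so the semantics cannot drift. Glycine has no Cβ; the package falls
back to Cα and flags the substitution. The 6 Å default is the
conventional side-chain interaction distance for this analysis and is a
plain argument, not a constant.

Helix membership (H1–H25 of the TPR-like solenoid) is supplied as a
label/start/end table with inclusive bounds, not recomputed from
coordinates: secondary-structure assignment would add a heavy dependency
and a second source of disagreement, while the published helix ranges
are short and stable.

## The synthetic-data generator

`gen_alignment()` emulates the statistical structure of a grouped family
alignment with known truth. Default study conditions mirror the
motivating dataset: three clades of 11, 7 and 9 sequences, a 700-residue
domain, four planted universal columns plus the motif planted at column
448, an upstream histidine in 90% of sequences, and a 2% per-cell gap
rate. Design choices that matter:

* **Background.** Uniform over the 20 residues, *excluding the motif's
  literal letters whenever a motif is planted*. With cysteine in the
  background at 1/20, a 700-residue sequence has expected ≈0.09 chance
  matches of `C.C..C` per sequence — enough to corrupt uniqueness
  bookkeeping across a 27-row alignment. Excluding the literals makes
  the planted motif provably unique, so `n_with_unique_motif` measures
  the scanner, not background noise. The background distribution is
  overridable for studies of chance-match rates.
* **Gaps are deletions.** A gap replaces a residue at a (row, column)
  cell, so alignment columns are stable while residue numbering shifts
  per row — exactly the situation `column_to_residue()` must handle.
  Planted columns and the whole motif stretch (context window through
  pattern end) are gap-protected so the ground truth stays exact; in
  particular, a gap *between* the context window and the anchor would
  silently change the histidine's residue-coordinate offset.
* **Context planting is exact-count.** `fraction_with_context = 0.9`
  plants the histidine in `round(0.9 n)` rows chosen at random, rather
  than by independent coin flips. The generator's job is to realize
  stated conditions exactly; sampling variation is then contributed (and
  tested) by the survey machinery, not compounded by the generator. With
  27 rows the realizable fraction is 24/27 ≈ 0.889.
* **Planted-column interactions.** Group-specific columns are forced
  non-identical in other groups; class columns sample within their class
  but outside the motif literals. Degenerate context settings (all rows,
  a single fixed offset) pin the context residue to one column, which
  the ground truth then counts as universal.

The generator does **not** emulate phylogenetic correlation (no tree, no
substitution model), realistic indel length distributions (gaps are
independent single-column events), compositional bias, or real side-chain
geometry (structures are ideal helices: 1.5 Å rise, 100° twist, 2.3 Å
radius, Cβ 1.53 Å radially outward — conventional α-helix parameters).
Consequently, passing recovery tests demonstrates that the pipeline's
bookkeeping is exact under controlled truth; it does not certify
performance on real families, where alignment quality dominates.

## Numerical and degenerate-input choices

* Conservation requires ≥ 2 members per group; smaller groups are a
  configuration error, not a silent identity call.
* Ragged alignments, empty FASTA records, illegal residue characters,
  unknown chains, and insertion codes all fail fast with classed errors
  (`sepmotif_alignment_shape_error`, `sepmotif_empty_input`, …) so
  callers can map them to exit codes (the CLI uses 0/2/3).
* PDB alternate locations resolve by highest occupancy, ties by file
  order; only the first MODEL and ATOM records are read.
* Contact computation with fewer than two resolved positions returns an
  empty table with a warning rather than an error — an almost-fully
  disordered query is an answer, not a failure.
* Survey clades with zero sequences are dropped with a warning; rows
  without a motif hit are listed as `missing` in the consistency report,
  not errored, since motif absence is a biological observation.

## Problem sizes in the test suite

The suite verifies each operation against an independent brute-force
oracle (naive per-residue profiling, sliding-window matching, all-pairs
distance filtering) on hundreds of fuzzed small instances (alignments up
to 10×50, sequences up to 200 residues, point sets up to 25), and runs
full planted-truth recovery over 50 seeded simulations with alignments up
to ~30×800 — sizes chosen to exercise every code path many times while
keeping a complete run in well under a minute per file. The survey
statistic is checked by pooling 20 seeded simulations of 30 sequences at
a 90% planted context rate against the binomial 95% interval.

## Known limitations

* Reproduction of published column sets from real alignments depends on
  the exact input alignment; minimal manual edits in published figures
  are not reconstructable from the methods alone.
* The "expected location" of a motif across distant clades is reported
  (coordinates, column consistency) but not enforced as a filter.
* Entropy- or tree-weighted conservation scores are out of scope; the
  profile is deliberately the simple per-group state model above.
* Solvent accessibility and interface analyses are not computed; the
  package maps conservation onto coordinates but does not interpret
  burial.
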