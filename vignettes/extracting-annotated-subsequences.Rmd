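---
title: "Extracting annotated subsequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting annotated subsequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneharvest)
```

## The procedure

geneharvest recovers individual loci from multi-gene GenBank records in
four steps: parse the flat file, match each annotated feature against a
synonym table, resolve the matched feature's location to a subsequence,
and serialize per-locus FASTA plus a species × locus accession table. The
method is annotation-driven: it trusts the feature table rather than
sequence similarity, which makes it exact where annotations exist and
blind where they do not (see *Limitations*). Its two substantive
ingredients are the location-grammar semantics and the matching rules;
everything else is careful bookkeeping.

### Location semantics

A feature location is decoded into an ordered list of
`(interval, strand)` segments in *assembly order* — the order in which the
mature sequence is concatenated:

* `join(a, b)` keeps listed order; each segment may carry its own
  `complement(...)`, which is how trans-spliced genes on opposite strands
  are annotated.
* `complement(join(a, b))` means "reverse-complement the joined plus-strand
  sequence", i.e. `revcomp(seq[b])` followed by `revcomp(seq[a])`. The
  parser normalizes this to segments `(b, minus), (a, minus)`, so one
  resolution rule covers both spellings: concatenate segments in stored
  order, reverse-complementing minus-strand ones. The test suite checks
  this normalization against an independent per-base oracle that walks the
  grammar position by position, over 1,000 random location strings.
* Partial markers `<` and `>` never change the numeric bounds; they are
  kept as flags and surface as the `partial` column of extraction output,
  so trimmed genes remain identifiable without being silently altered.
* `order(...)` makes no assembly promise, but the listed order is the only
  defensible reading; it is treated as `join(...)` and a warning issue is
  attached rather than refusing the record.
* Between-base locations (`102^103`) and remote-accession references
  (`J00194.1:1..100`) are hard errors naming the offending span. Extracting
  something subtly wrong is worse than failing loudly; the affected locus
  is reported as `unparseable_location` and other loci are unaffected.

### Matching rules

A term row `(Locus, Type, Name)` matches a feature when the feature key
equals `Type` (case-insensitive) and `Name` equals one of the feature's
qualifier values. Decisions that were genuinely open, and the choices made:

* **Whole-value matching by default.** The qualifier value is compared
  case-insensitively after trimming, as a whole. Substring matching would
  let `COI` swallow `COIII`; gene symbols are short and prefix-heavy, so
  anchored comparison is the safe default. A `word_boundary` mode is
  offered for fishing synonyms out of long product strings
  ("putative COI protein"), where whole-value matching is too strict.
* **Qualifier precedence** is `gene` > `product` > `standard_name` >
  `note`, configurable. Gene symbols are the most specific annotation;
  notes are free text and matched last.
* **Row order is match priority.** When one feature could satisfy rows of
  two loci, the first table row wins. This makes precedence user-visible
  and editable: reorder the table to change it.
* **`D-loop` rows match by feature key alone.** The control region
  commonly carries no name qualifier at all, so requiring one would lose
  it; an empty `Name` is legal only for this type.
* **`gene` features are a fallback, not a peer.** A CDS and its enclosing
  `gene` feature describe the same locus; consulting `gene` features only
  for loci nothing else matched avoids extracting the same region twice
  while still recovering records annotated with bare gene features.
* **Intron/exon rows** dispatch on the feature's `/number` qualifier
  equaling the row's `IntronExonNumber`, plus the synonym when one is
  given. Introns missing from a feature table are reported `not_found` —
  they cannot be conjured from annotations that do not exist.
* A feature's own `/transl_table` overrides the configured default genetic
  code: the record's self-description is more trustworthy than a global
  flag.

### Translation

NCBI codes 1 (standard), 2 (vertebrate mitochondrial), 5 (invertebrate
mitochondrial) and 11 (plastid/bacterial) are implemented as explicit
64-codon tables — the codes relevant to the bundled dictionaries — and
verified codon-by-codon against `Biostrings::getGeneticCode` in the tests.
Other table numbers raise an error listing the supported codes rather than
silently falling back to the standard code. `codon_start` skips 0–2
leading bases; an incomplete trailing codon is dropped; exactly one
terminal stop is removed when present. Internal stops are *retained* as
`*` and counted in the report note instead of aborting: annotation errors
are a known hazard of public records, and flagged output supports the
user's own due diligence better than a refusal. Codons containing
ambiguity codes translate to `X`.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `match_mode` | `exact_full_value` | prevents prefix collisions (COI vs COIII) |
| `qualifier_search_order` | gene, product, standard_name, note | specificity order |
| `transl_table` | 1 (bust CLI), per-feature override always wins | least-surprise default |
| `duplicates` | off | one sequence per locus unless copies are requested |
| FASTA header | `organism_accession` | downstream supermatrix rows are species |
| FASTA wrap | 80 columns | any fixed wrap is valid; fixed for byte-exact tests |

Tie-breaks are all deterministic: first matching table row, first found
accession per (species, locus) cell (with a warning counting the
conflicts), and lexicographically least accession for equal-length
`find_longest_seq` candidates, which makes the selection invariant to
input order.

## The synthetic world

`generate_fixture()` emits flat files with every locus of a term table
planted as an annotated feature, plus a manifest of the exact subsequence
each must yield. Defaults state the test world: 50% minus-strand features,
20% spliced (`join`), 5% trans-spliced with mixed strands, 10% partial
markers, 10% duplicated loci, and decoys (near-miss names such as
`COX1 pseudogene`) at 20% of the locus count. Planted CDS start `atg`,
avoid internal stops under every shipped code, and end `taa` so
translation tests are meaningful; organisms are synthesized as
`Genus_i species_j` with fewer species than records, so multi-accession
grouping and longest-per-species selection are exercised. All randomness
flows from one seed; identical specs are byte-identical.

What the generator emulates: the location grammar in all supported forms,
synonym variability (each planted feature is annotated under one randomly
chosen synonym of its locus), duplicate gene copies, and the documented
real-world failure modes via `degrade_fixture()` — records that only state
"contains genes X, Y, Z" with no per-gene positions, and records whose
control region is absent from the feature table entirely.

What it deliberately does not emulate: realistic base composition (bases
are uniform), realistic gene lengths (features are 60–300 bp so large
fixtures stay inside test budgets; the record in the acceptance run is
~17 kb rather than organelle-genome scale), overlapping genes, qualifier
line-wrapping idiosyncrasies of real submissions, and annotation *errors*
other than the degraded modes. A green planted-recovery test therefore
establishes that matching and location resolution are exact under the
grammar — not that any particular public record is annotated correctly,
which no offline tool can establish.

## Numerical and degenerate-input choices

* Sequences are canonicalized lowercase; qualifier values are preserved
  verbatim. Determinism for byte-exact tests.
* The writer emits each qualifier on a single line and reuses a location's
  original raw text. Round-tripping is exact for canonical records;
  records whose location used `order(...)` re-parse with the same warning
  issue, by design.
* A record whose declared LOCUS length disagrees with its sequence, or
  whose features exceed the sequence bounds, parses with an `error` issue
  attached (nothing is dropped) but is refused by the writer.
* An empty input stream yields empty outputs; a stream without a final
  `//` yields a best-effort record plus an error issue.
* `merge_terms` deduplicates on all-field equality, case-sensitively:
  `cox1` and `COX1` are distinct synonyms, both kept.

## Limitations

* Only annotated loci can be extracted; unannotated introns and intergenic
  spacers (e.g. trnH–psbA) are invisible to this method, as is anything a
  submitter mislabeled. Sequence-similarity retrieval is a complementary,
  out-of-scope approach.
* No network retrieval of any kind; records are local files by contract.
* Genetic codes other than 1, 2, 5, 11 are not shipped.
* Between-base and remote-accession locations are rejected, not resolved.
* The bundled dictionaries were compiled from common INSDC usage; they are
  starting points meant to be extended with `merge_terms()`, not exhaustive
  synonym inventories.
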