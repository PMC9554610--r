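---
title: "Inferring host-MGE interaction networks from CRISPR spacers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring host-MGE interaction networks from CRISPR spacers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crisprnet` infers putative interactions between bacterial hosts and
mobile genetic elements (MGEs: phages and plasmids) from the immune
memory stored in CRISPR arrays, and summarises them as bipartite
networks. This vignette explains the models and procedures behind each
stage, the parameters that matter, the design choices that were
genuinely open, and what the synthetic benchmarks do and do not
demonstrate about real data.

## CRISPR array detection

A CRISPR array is a run of near-identical *repeats* (typically 23–55 bp)
separated by variable *spacers* (typically 18–72 bp), most of which are
copies of past invaders' DNA. The package offers two detectors.

**De novo.** The detector is in the CRT/PILER-CR family: it seeds on
exact k-mers (`seed_k`, default 13 bp) that recur with a CRISPR-like
period — successive occurrences between `min_repeat_len +
min_spacer_len` (41 bp) and `max_repeat_len + max_spacer_len` (127 bp),
within a `window` of 500 bp — then extends each seeded column set
outwards while the column is identical across all units, subject to the
repeat-length cap and the requirement that every remaining gap (the
spacers) stays at or above `min_spacer_len`. Runs are split wherever a
gap leaves the legal spacer-length range, candidates from different
seeds inside the same repeat are deduplicated, and overlapping
candidates are resolved in favour of more repeat units. At least
`min_repeats` units (default 3, i.e. two spacers) are required.

Because extension stops at the first column where the units disagree,
reported repeats are exact copies of the consensus. This is the right
bias for the package's main use — spacers feeding a downstream match —
since a conservatively bounded repeat can at worst transfer one or two
boundary bases into each spacer, which the coverage filter absorbs,
whereas an over-extended repeat would truncate every spacer.

A consequence worth stating precisely: if every unit of an array is
followed by the *same* base (all spacers plus the downstream flank start
with, say, `G`), the repeat/spacer boundary is not identifiable from the
sequence alone, and this detector — like any repeat-based detector —
will place that column inside the repeat. The planted-array helper
`plant_crispr_contig(identifiable = TRUE)` therefore adjusts at most the
two flank bases adjoining the array so the boundary columns are
polymorphic; this makes "exact recovery of planted spacers" a
well-posed benchmark rather than a coin flip on boundary-base
coincidences. The full simulator does *not* do this, because a 1-bp
boundary clip is immaterial for interaction recovery (a 31/31-identity,
31/32-coverage hit still clears every filter).

**Guided.** When repeats of the CRISPR-Cas systems of interest are
known, the guided detector scans both strands with a sliding-window
Hamming match against each library repeat (`max_repeat_mismatch`,
default 3 substitutions — repeats must be "identical or very similar",
and gapped variation in such short units is rare), chains matches whose
gaps are legal spacer lengths, and tags resulting arrays with the
library entry's CRISPR type (e.g. `I-C`, `II-C`, `V-A`). Arrays matched
on the minus strand are reported with repeats and spacers
reverse-complemented and their order reversed, so spacer order always
follows the repeat orientation; under this normalisation the reported
spacer set of a contig is invariant under reverse-complementing the
contig, which is the property the test suite asserts. CRISPR type is
metadata only: the package does not call *cas* genes and accepts type
labels from the repeat library.

**Artifact filtering.** Tandem repeats and other periodic sequence mimic
the repeat–spacer structure but their "spacers" are similar to each
other and/or to the repeat, whereas genuine spacers are essentially
random with respect to one another (expected pairwise identity ≈ 0.25
for uniform DNA). `filter_artifacts()` removes an array when the mean
pairwise spacer identity exceeds `spacer_sim_cutoff` (0.60) or the mean
spacer-to-consensus identity exceeds `repeat_spacer_sim_cutoff` (0.60).
The cutoffs sit far above the random baseline (≈ 0.25) and far below
true repetition (≈ 1.0), so their exact values are uncritical; identity
between unequal-length sequences is computed ungapped over the shorter
length with the longer length as denominator.

**Deduplication.** "100% non-redundant" spacer clustering is
implemented as exact duplicate collapse after uppercasing, with an
`exact_rc` mode that also merges a sequence with its reverse complement
(representative: the lexicographically smaller orientation). Substring
containment is deliberately not collapsed: two spacers of different
lengths are different immune acquisitions, and containment semantics
would make cluster counts depend on detection boundary details.

## Protospacer search and e-values

The search finds, for each spacer cluster, the database loci it could
have been acquired from. Seeding uses exact shared words on both
strands; each seeded diagonal is evaluated as the *full-query-span
ungapped alignment* — identity is measured over the entire projection of
the spacer onto the subject, so terminal mismatches count. This is the
statistic the retention filters are phrased in: a 32-bp spacer with 3
substitutions has identity 29/32 = 90.6% wherever the substitutions
fall, and with 4 substitutions 28/32 = 87.5%. A maximal-scoring local
alignment would instead trim a terminal mismatch and report 28/31 =
90.3% — silently moving a hit across the 90% threshold. The trimming
behaviour is available as an option (`gapped = TRUE`, a Smith–Waterman
refinement via `Biostrings::pairwiseAlignment` under the same scoring
scheme), which is the right tool when indel-containing protospacers
matter; it is off by default because the mutation model of interest is
substitution-dominated and the filter semantics above are exact for it.

Scoring is +1/−2 with affine gap penalties 5 (open) and 2 (extend) in
gapped mode — the usual choice for short, near-exact nucleotide matches.
The default word size is 8 bp rather than the 11 bp of general-purpose
nucleotide search: a spacer at the 90%-identity boundary (3 substitutions
in 32 bp) is only *guaranteed* to retain an exact run of
⌈29/4⌉ = 8 bp, so an 8-bp word makes seeding exhaustive for every hit
that can pass the filter, while 11 bp would miss some legitimate
boundary hits. (Word sizes of 7 are standard for short-query nucleotide
search.) Overlapping candidate loci for the same (cluster, MGE, strand)
are merged keeping the best raw score, ties to the leftmost subject
position, so each hit is one locus.

Significance follows Karlin–Altschul statistics under uniform base
composition: λ is the unique positive root of

$$\tfrac14 e^{\lambda\,\mathrm{match}} + \tfrac34 e^{\lambda\,\mathrm{mismatch}} = 1,$$

solved numerically (for +1/−2, λ ≈ 1.3327), and a raw score $S$ maps to
bit score $(\lambda S - \ln K)/\ln 2$ and e-value $K\,m\,n\,e^{-\lambda S}$
with $m$ the spacer length and $n$ the total database length. $K$ is a
configurable constant (default 0.46, the standard ungapped nucleotide
value): computing $K$ exactly would change e-values by a small constant
factor, which is immaterial three orders of magnitude below the 0.001
threshold, whereas λ sets the exponential slope and is therefore derived,
not assumed. No edge-effect correction is applied to $m$ and $n$; at
these thresholds it would be invisible. The e-value is monotone —
strictly decreasing in score, linear in database size — and both
properties are tested.

Retention keeps a hit iff identity > 0.90 **and** query coverage per HSP
> 0.80 **and** e-value < 0.001, all strict inequalities. Externally
produced hits in the 12-column tabular convention can be ingested
instead of the built-in search; coverage is recomputed from the query
span and spacer length, strand inferred from the subject coordinates.

## Greedy covering-set selection

MGE databases are highly redundant, so connecting every matched MGE
would clutter the network without adding information. The selection rule
is the classic greedy set-cover approximation: the universe is the set
of matched spacer clusters; each MGE covers the clusters it holds
protospacers for; repeatedly select the MGE covering the most
not-yet-covered clusters until all are covered. The same rule, with
hosts as candidates covering the matched clusters their spacers belong
to, thins the host side. Properties:

* every selected candidate contributes at least one new cluster;
* the selection size is within $(1 + \ln d)$ of the exhaustive optimum
  ($d$ = largest candidate set) — verified against brute-force
  enumeration on random instances;
* ties are broken by lexicographically smallest id, making the whole
  pipeline deterministic under any input iteration order (the choice
  among equally good candidates is otherwise arbitrary, and
  reproducibility is worth more than any particular arbitrary pick).

Two open readings were settled as follows. The cover universe is
*matched spacer clusters*, not individual protospacer loci: the network
semantics only require every matched spacer to be explained by at least
one selected MGE, and locus-level coverage would re-introduce exactly
the redundancy the step removes. Host selection likewise covers matched
clusters only: a host none of whose spacers match anything cannot
appear in a network whose every node must have an interaction, so
including unmatched spacers in the host universe would either be a
no-op or force uncoverable instances. Phages and plasmids compete in a
single greedy pool, which is what allows mixed selections.

## Networks, components and export

Both networks are undirected bipartite graphs. In the spacer–MGE
network, nodes are matched spacer clusters (attribute: CRISPR type,
`untyped` when unknown) and selected MGEs (class, source collection,
known-host annotation); an edge means the MGE contains at least one
passing protospacer for the spacer, with `nmatches` counting distinct
loci. In the host–MGE network an edge joins a selected host and selected
MGE sharing at least one matched cluster, `nmatches` counting distinct
(cluster, locus) pairs. Every node has degree ≥ 1 by construction.

Connected components are computed with igraph and numbered by
decreasing node count (ties: lexicographically smallest member), and
each component's composition — spacers per CRISPR type, hosts, phages,
plasmids — is reported so that type-biased modules (e.g. a module whose
spacers are almost all from one CRISPR-Cas type, suggesting differential
activity of that system against those invaders) can be read directly
from `components_*.tsv`. Networks are written as GML with a pinned
`Creator` line (the library default embeds a timestamp, which would
break byte-level reproducibility) and round-trip losslessly through
`read_network()`; node/edge TSVs are available for Cytoscape table
import.

## The simulator: what it emulates and what it does not

`simulate_dataset()` generates the statistical structure the method
assumes: MGEs are i.i.d. uniform DNA; each host contig is random flanks
around arrays of a library repeat alternating with 32-bp spacers; each
genuine spacer is a segment of a random genuine MGE (either strand)
mutated by independent substitutions; decoy MGEs are never sampled, and
a configurable fraction of spacers are uniform random decoys. The
defaults (20 hosts, one array of 3–8 spacers each, 50 genuine + 10
decoy MGEs of 2–4 kb, substitution rate 0, 10% decoy spacers, 15%
plasmids) are the scale at which end-to-end recovery is benchmarked; at
rate 0 every ground-truth host–MGE pair must be recovered and no decoy
may appear in any network.

The mutation model is substitutions only — no indels. This is
deliberate: the identity and coverage filters act on Hamming-type
divergence, and the 3-vs-4-substitution boundary (29/32 vs 28/32) is
exercised exactly; indel support in the mutation model (paired with
`gapped = TRUE` search) is a natural extension. Decoys are uniform
random DNA rather than shuffled genuine sequence, which makes the
false-positive analysis self-contained (a 29/32 match to 32 bp of
random DNA essentially never occurs by chance) but also means the decoys
are *easy*: real databases contain homologous families, and the
simulator does not emulate composition bias, repeat families crossing
MGEs, prophage-contaminated host contigs, or PAM structure. Passing the
synthetic benchmarks therefore demonstrates correctness of the
machinery — detection geometry, filter boundaries, cover logic, network
assembly, determinism — not field performance on real metagenomes,
where database completeness dominates (in published applications of
this kind of pipeline, the fraction of spacers with any database match
ranges from roughly a fifth to three quarters depending on how well the
environment is represented).

## Numerical and interface conventions

* Coordinates are 1-based inclusive everywhere (the R/Bioconductor
  convention); minus-strand hits have `s_start > s_end`, following the
  tabular alignment convention.
* All randomness in the simulator derives from one seed through R's
  Mersenne-Twister generator; identical configuration and seed give
  byte-identical output files, and the pipeline itself is
  deterministic, so re-runs are byte-identical too.
* Degenerate inputs degrade gracefully: contigs too short to hold an
  array are skipped; genomes with no arrays produce a zero-count
  manifest and valid empty artifacts; spacers shorter than the word
  size are skipped with a warning; an uncoverable universe (possible
  only with inconsistent external inputs) is an error listing the
  uncovered elements; any stage failure aborts with the stage name.
* Problem sizes used in the checked benchmarks: 100 planted contigs for
  array recovery; 50 spacers × 20 MGEs for the search-vs-oracle
  comparison; 200 replicates at the identity boundary; 200 random cover
  instances (≤ 12 candidates, ≤ 20 elements) against exhaustive
  enumeration; a ~1000-node graph against a BFS oracle; ten simulated
  datasets at the default scale for end-to-end recovery. These sizes
  make every property a near-certain discriminator while keeping the
  whole suite fast on a single CPU.

## Known limitations

* No *cas*-gene annotation or CRISPR-Cas subtype calling; type labels
  come from the repeat library or user metadata.
* The de novo detector requires exact repeat copies within an array (up
  to the consensus-extension rule); heavily degenerate terminal repeats
  are truncated rather than modelled.
* Ungapped search by default; indel-containing protospacers need
  `gapped = TRUE`.
* E-value calibration is ungapped Karlin–Altschul with a fixed $K$; no
  composition-based adjustment or low-complexity masking.
* The greedy selection deliberately discards redundant MGEs; interactions
  involving non-selected MGEs remain available in `hits_filtered.tsv`.
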