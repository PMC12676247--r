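---
title: "phagenet: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagenet: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`phagenet` implements the decision rules and algorithms that turn a large
collection of annotated contigs into a curated phage genome set and an
ecological interaction map: viral triage, species-level ANI clustering,
alternative genetic-code detection, iterative core-marker phylogenies,
genus-level AAI clustering with a habitat-divergence test, and
CRISPR-spacer interaction networks. External tool stages that the original
workflow delegates to trained models or HMM/BLAST engines (gene callers,
k-mer classifiers, completeness estimators, HMM searches, heuristic
aligners) are represented by their *outputs* — score columns, family
assignments, annotation tables — not reimplemented. What remains is the
bespoke logic, which is what this package tests.

# Triage

Four viral-evidence predicates are computed per contig: (1) viral
protein-family hits present with zero microbial-family hits; (2)
nucleotide-classifier score ≥ 0.9; (3) strand switch rate ≤ 0.25 over ≥ 4
genes (compact, co-oriented gene runs are a viral signature); (4) viral
hits strictly exceeding microbial hits. How the four signatures combine
into one call is genuinely open; we adopt a configurable *k-of-4* rule
(default k = 2), which keeps every threshold auditable and exposed in
`viral_signature_thresholds()`. The hallmark-keyword rule, the BUSCO/VPF
false-positive filter and the quality gates are fixed rules and are
implemented exactly; two boundary decisions were open and are resolved as
follows:

* a BUSCO ratio of exactly 0.067 falls between "< 0.067" and "> 0.067";
  we route it to the VPF-rescue clause so every genome is classifiable;
* keyword matching is case-insensitive substring over whole descriptions;
  short terms ("neck", "head", "T4") can over-match inside longer words —
  accepted for fidelity to the published term list.

# Species-level clustering

`pairwise_ani()` is a gapless seed-and-extend ANI: exact 15-mers seed
diagonals on both strands, seed runs are chained while the spanned
identity stays ≥ 70%, chains are extended as far as cumulative identity
allows, and ANI is the alignment-length-weighted identity over retained
segments; coverage uses merged intervals, so overlaps are not double
counted. Substitution-level divergence is handled exactly (one planted
substitution per 50 bp moves ANI by exactly its count); indels are *not*
chained across diagonals — a stated desk-scale limitation, adequate
because the synthetic world mutates by substitution only. Two noise
guards matter numerically: diagonals supported by a single seed 15-mer
are dropped when sequences are long enough to expect dense seeding, and a
single-seed segment is additionally required to reach 80% identity
(structured low-complexity repeats can otherwise extend a chance seed to
a marginal ~70%-identity segment and bias ANI downward by ~0.5–1 point).

Greedy clustering sorts genomes by length (descending, ties
lexicographic) and absorbs unassigned genomes at ANI ≥ 95% and **member**
coverage ≥ 85%. Coverage of the member (the shorter/contained genome) is
the convention that lets genome fragments join their parent species; the
alternative readings (coverage of both, or of the centroid) would orphan
fragments.

# Alternative genetic codes

`find_orfs()` is a deliberately simple six-frame caller: ORFs run from
the first start codon (ATG/GTG/TTG) after the previous in-frame stop to
the next stop, run-off ORFs at sequence ends are counted, and the minimum
length is 90 nt. Only stop-set membership differs between the four
candidate codes, so a trained gene model would add realism but not change
the contrast the decision rule measures. Coding density is defined as
*union* coverage of ORF intervals over genome length: bounded by 1 and
provably monotone under stop-set reduction, which gives the key
invariant (density under any proper stop subset ≥ density under the full
stop set) a clean proof and a cheap property test.

"Increased > 10%" is read as a relative gain, `(d_alt − d11)/d11` —
matching the comparative phrasing — with the absolute-difference reading
available via `gain_mode = "absolute"`. Ties among qualifying codes break
in the fixed order 15, 90, 91. The published code↔codon mapping is
internally inconsistent between its methods and results sections; we
follow the methods-section mapping (15: TAG, 90: TAA, 91: TGA recoded)
and flag, rather than resolve, the conflict.

# Marker phylogenies

Core-profile selection, column trimming and the genome-inclusion rule are
exact rule implementations. Two readings were open: "markers present in
> 5% of alignment columns" is computed per marker (against that marker's
trimmed width), not against the concatenated width; and "genomes not
placed in the tree" maps to failure of the inclusion rule. Maximum-
likelihood tree inference is out of scope; `nj_tree()` (neighbor joining
on concatenated-marker p-distances over shared non-gap columns) preserves
the pipeline's distance semantics and recovers additive matrices exactly,
which makes it oracle-testable. NJ can produce slightly negative branch
lengths on non-additive input; they are clamped to zero to keep the tree
a valid metric source. Genome pairs sharing no alignment columns receive
a fixed p-distance of 0.75 (the random-sequence expectation's saturation
bound). `mean_copy` averages over genomes that contain the profile — the
stricter reading; the prevalence denominator is the full genome set.

# Genus clustering and habitat divergence

AAI shared genes are reciprocal best matches by global BLOSUM62 alignment
score, gated by positive score *and* ≥ 30% identity — the twilight-zone
floor; without it, random unrelated proteins yield nonzero shared
fractions, contradicting the contract that disjoint random gene sets
share nothing. `shared_frac` uses the smaller genome's gene count as
denominator (config-switchable).

The published threshold sentence literally clusters pairs *below* 50%
AAI / 20% shared genes; we treat that as a typo and connect pairs
*meeting* the thresholds — the standard genus-graph convention — with
both thresholds exposed. Markov clustering is the standard
expansion/inflation iteration (inflation 2.0, column-stochastic,
convergence at max change < 1e−6 or 200 rounds, attractor-based
extraction); it never merges disconnected components.

The divergence test compares same-habitat vs cross-habitat patristic
distances with a one-tailed Wilcoxon rank-sum test (exact enumeration for
tie-free samples up to 20 observations, otherwise the normal
approximation with tie and continuity corrections). "Two one-tailed
tests" reduces to the single direction the designation rule uses
(cross > same); the complementary p-value is reported for completeness
but unused. Note a structural floor: the minimal eligible cluster (4
genomes, 2 + 2 habitats) has only 2 same-habitat and 4 cross-habitat
pairs, so the smallest attainable exact p is 1/15 ≈ 0.067 — such clusters
can never be called divergent at α = 0.05. Pairwise distances from one
tree are dependent observations; empirically the test is *conservative*
under label permutation (type-I error ≈ 0.01 at α = 0.05 on coalescent
null trees), which the calibration test asserts as an upper bound only.

# CRISPR networks

The array detector finds maximal runs of ≥ 3 *exact* copies of a repeat
(23–47 nt) separated by unique spacers (26–50 nt), seeded from recurring
23-mers and extended while all copies agree; overlapping candidates
resolve by most copies, then leftmost. Real detectors tolerate repeat
degeneracy; exactness is a documented simplification. Spacer matching is
an exhaustive bounded-mismatch scan — every offset, both strands,
full-length, ≤ 1 mismatch, `N` matches nothing — because the published
acceptance rule is exactly computable and a heuristic aligner would only
add approximation. Spacer hits that land inside the target's own array
are shared immunity, not predation, and are excluded from phage–phage
targeting (disable with `exclude_array_hits = FALSE`). "Same host" for
targeted pairs intersects genus-level host sets; the acquisition module
counts as complete with Cas1 + Cas2, Cas4 being recorded but not
required (several complete acquisition modules lack it).

# The synthetic community

`generate_community()` plants a world whose structure mirrors the
statistical assumptions of every stage: species groups at 2% within-group
divergence nested as habitat lineages (12% divergence) inside genus
groups; a fraction of genomes rebuilt with a reassigned stop codon; hosts
carrying CRISPR arrays whose 32-nt spacers are copied from phage genomes
with 0 or 1 planted mismatches (half in reverse complement); and a
fraction of phages carrying arrays that target other phages. A single
seeded Mersenne–Twister stream with fixed generation order makes output
byte-identical across runs and platforms.

Three construction devices keep the planted signals exact, and are worth
knowing because they are what a green test does and does not establish:

* **Frame guards and stop units.** Gene bodies interleave 16-codon guard
  blocks whose off-frame and reverse-strand readings contain at least two
  stop types in every frame class, and intergenic regions consist of stop
  units carrying all three stop codons (and all three reverse-complement
  patterns) adjacently in every frame class, twice over. Together these
  pin coding density to the planted gene structure under *every*
  single-stop-reassignment code: stop positions are nearly code-independent
  (all three types within 9 nt), so density contrasts come only from
  planted recoding. Free positions inside guards and units are randomised
  per occurrence so repeated elements never share a 15-mer (ANI seeding
  stays clean) and intergenic draws are rejected if any 23-mer repeats
  (which would mimic a CRISPR repeat).
* **Purifying selection.** Member mutation reverts substitutions that
  would create an in-frame stop inside a gene or destroy a start or
  terminal stop codon — the constraint real coding sequence evolves
  under. Without it, lineage-level mutation fragments reading frames
  asymmetrically across stop sets and produces spurious ~10% density
  gains on non-recoded genomes.
* **Exact link truth.** Spacers are sampled from reserved, non-overlapping
  windows (per genus group, since lineages share the genus coordinate
  system), and the final link tables are produced by a generator-internal
  exhaustive scanner, because a spacer copied from one species member
  legitimately matches its near-identical siblings. Genomes from other
  genus groups are independent random sequence (full-length ≤ 1-mismatch
  match probability ~4⁻³⁰) and are only guarded against exact collisions.

What the generator does *not* emulate: realistic gene content, GC skew or
codon usage; indels and rearrangements (so the ANI engine's
substitution-only assumption is never challenged); degenerate CRISPR
repeats; read-level artefacts. Green recovery tests therefore establish
the correctness of the decision rules and algorithms on their stated
inputs — not robustness to assembly noise or model misspecification.

Default world parameters: 40 phages of 8–12 kb in 8 species groups and 3
genus groups (half divergent with habitat-following lineages, half with
shuffled habitat labels), 10 hosts of 20–30 kb, 10% recoded phages, 32-nt
spacers, 3 spacers per host array, 20% of phages carrying 2-spacer
arrays, strand switch rate 0.1, 30% reference-set membership. Metadata
marks every phage as having an external spacer match (standing for
matches against prokaryote spacer catalogues beyond the simulated hosts),
so the keyword rule's spacer clause is exercised by the planted host
arrays and the flag together.

# Numerical conventions

Coordinates are 1-based inclusive throughout; `N` never matches any base;
ambiguity codes collapse to `N` on input with a warning. Percentages are
rounded half-up to 2 decimals (`proportion_pct()`), the convention that
reproduces every count-consistent published proportion. Wilcoxon p-values
are clamped to (0, 1] and degenerate (zero-variance) data returns 1.
Reported p-values switch from exact enumeration to the corrected normal
approximation above 20 combined observations; at that boundary the two
agree to < 0.01.

# Known limitations

* ANI ignores indels and rearrangements; coverage and identity are exact
  only for substitution-divergent genomes.
* The ORF caller has no start-codon scoring or RBS model; coding-density
  contrasts, not gene models, are the deliverable.
* The CRISPR detector requires exact repeat copies and single-interval
  arrays.
* The divergence test treats pairwise tree distances as a rank sample;
  dependence makes it conservative rather than exact.
* MCL is dense-matrix; fine for hundreds of genomes, not for millions.
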