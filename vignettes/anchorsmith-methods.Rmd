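---
title: "Anchored hybrid enrichment design and processing: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored hybrid enrichment design and processing: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models behind `anchorsmith`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the procedure left genuine freedom.

## The matching model

Every detection step in the pipeline — genome scanning for anchor targets,
read recruitment, and extension assembly — uses the same two-stage gapless
criterion:

* **Seed**: a window of `seed_window` (20) bases matches a reference window
  when at least `seed_min_matches` (17) compared positions are identical.
  The comparison template is a *spaced seed*; the default is all-care (a
  contiguous 20-mer with a 3-mismatch budget). The template published for
  the original implementation is not reproduced in its paper, so the
  all-care default is a documented stand-in; arbitrary care masks are
  accepted by `seed_match()`.
* **Confirmation**: the best gapless window of `confirm_window` (100) bases
  containing the seed must reach `confirm_min_matches` (55) identities.
  When the window is clipped by a sequence end, the threshold scales
  proportionally (a 60-base overlap needs `55 × 60/100 = 33` identities).
  Two readings of a "consecutive" confirmation are implemented: the default
  `aligned` mode counts identities anywhere in the window; `consecutive`
  mode additionally demands a single exact run of `confirm_min_matches`
  bases. The aligned reading is the default because the exact-run reading
  rejects genuine homologs at even modest divergence (an exact 55-mer
  requires roughly `0.99^55 ≈ 0.57` survival even at 1% divergence, and
  essentially never survives 10%).

N (and any other non-ACGT character) never matches in seed or confirmation
space.

**Anchor acceleration.** The scanners locate candidate diagonals through
exact 12-mer anchors (a rolling-hash index over the references) and then
enforce the full seed-plus-confirmation contract on each candidate
diagonal. A true match at the divergences this pipeline targets contains
many exact 12-mers (a 250-base read at 15% divergence to its reference
expects ~25 of them), so acceptance is statistically indistinguishable from
exhaustive window enumeration, while decoy behaviour is identical — a
candidate that fails the 17-of-20 seed or the 55-of-100 confirmation is
rejected exactly as it would be in the exhaustive scan.
`seed_match()`/`confirm_match()` remain exact single-window operations.

Coordinates are 1-based closed inside the package (the R and IRanges
convention); BED export converts to the standard 0-based half-open form.

## Candidate windows

Validated genome hits on the same contig and strand lying within
`target_window` (10 000) bases of each other merge into one candidate
locus; the 10 kb window is centred on the merged hit span and clipped at
contig ends. Centring is a choice — the criterion "a 10 kb region
containing a hit" does not fix the registration — and merging is greedy
leftmost-first.

## Read processing and the extension assembly

Paired reads are merged at their best gapless overlap (most matches; at
least `min_overlap` = 12 bases and a mismatch rate ≤ `max_mismatch_rate` =
0.1). Within the overlap the higher-quality base wins, with quality
`max(q1,q2)` on agreement and `|q1−q2|` on conflict; adapter read-through
beyond the fragment ends is removed. Candidate overlap shifts are found by
exact 16-mer anchors shared between the reads, with an exhaustive-shift
fallback when no anchor exists; for any pair able to pass the 10% mismatch
gate the two searches choose the same shift.

Recruited reads seed one gapless cluster per locus (offsets only, no indel
realignment — reads carrying indels simply fail confirmation and are not
recruited). Extension then iterates: rebuild the working consensus
(majority base per site), re-scan the unassigned pool against it with the
same seed-and-confirm criterion, add hits at their offsets, stop when an
iteration adds nothing. Three design choices matter here:

* **Joint extension.** `extend_assemblies()` extends all of a sample's
  clusters against one shared pool, so a read joins the cluster it matches
  best and can never be claimed twice. The single-cluster
  `extend_assembly()` is the primitive; the joint driver is what the
  pipeline uses.
* **Ambiguity margin.** A read whose second-best placement scores within
  `ambiguity_margin` (5) identities of its best is rejected as ambiguous.
  With exact repeat copies in a genome, placements on different copies
  differ only by scattered sequencing errors; a margin of a few identities
  rejects those reads instead of letting them stack on an arbitrary copy.
* **Minimum extension depth.** The working consensus exposes only sites
  with depth ≥ `min_extension_depth` (3); lower-depth sites become N, which
  cannot seed or confirm. This is the standard assembler end-policy: it
  stops sparse off-target read chains from creeping the consensus outward
  and diluting the average-depth statistic that gates consensus calling.

Extension output is order-independent: the pool is processed in canonical
(id-sorted) order.

## The consensus model

A cluster yields a consensus only when its average depth — total aligned
bases divided by consensus length — **strictly exceeds** `min_avg_depth`
(250). The criterion's wording ("greater than an average of 250 reads")
is read as mean per-site read count, which equals that ratio; both the
ratio and the raw read count are available on the cluster object.

Per site with depth `n`: the majority base is always retained (a tie
retains all tied bases, giving a degenerate code); a minority base with
count `c` is retained iff the one-sided exact binomial tail
`P(X ≥ c | n, p = error_rate) < alpha`. Defaults: `error_rate` 0.01 — the
1% sequencing-error model, interpreted as the per-base probability of
miscalling *toward the observed base* (a conservative reading; dividing by
3 for a uniform miscall model would retain strictly more minority bases) —
and `alpha` 0.05, chosen because the source procedure states the error rate
but neither the test statistic nor a significance level. Both are
configurable. Zero-depth sites are N. The residue is the IUPAC code of the
retained set.

The implementation computes the tail with `stats::pbinom`; the test suite
re-derives the full decision grid (depths 50–1000, minority counts 0–20)
with an explicit log-space tail summation so the check does not share code
with the implementation.

## Orthology clustering

Distances are `1 − J` on canonical (strand-free) 20-mer *sets* — the
multiplicity-weighted variant is available behind a flag, since "degree of
20-mer distribution overlap" admits both readings, and the set reading is
the simpler one. Clustering is base R `hclust` (average linkage by
default; single linkage available) cut at `cluster_cutoff`.

The cutoff default is 0.995, and the reasoning is worth spelling out.
Orthologs diverged by a per-site distance `p` share roughly a `(1−p)^20`
fraction of their 20-mers, so at 10–15% pairwise divergence a true ortholog
pair retains only ~1–12% of shared 20-mers — Jaccard distances of about
0.92–0.99. Unrelated loci share essentially nothing (two random 1.5 kb
sequences collide in 20-mer space with probability ~10⁻⁶) and sit at 1.0
exactly. The informative boundary is therefore just below 1, not in the
middle of the range: 0.995 separates "shares a conserved core's worth of
20-mers" from "shares nothing", and keeps ortholog-recovery F1 ≥ 0.95
whenever the within-locus and between-locus distance distributions do not
overlap.

Each cluster containing a reference-tagged member becomes an ortholog
group; clusters without one are dropped and reported; a second sequence
from one sample is flagged as a paralog, keeping the member closer (mean
distance) to the rest of the cluster.

## Alignment QC

The automated trim/mask procedure and its boundary conventions:

| rule | threshold | boundary |
|---|---|---|
| reliable site (modal non-gap frequency) | 0.5 | inclusive — a 50/50 column is reliable |
| misaligned-run masking | 14 bases | inclusive — a 14-run masks, 13 does not |
| sparse-site removal (present sequences) | 25 | inclusive keep — 25 stays, 24 goes |
| sparse-locus filter (panel fraction) | 0.5 | strict removal of "< 50%" — 5 of 10 survives |

Runs are broken by agreement, gaps, unreliable sites and already-masked
cells. QC only masks or removes — it never rewrites a character — and the
identify → mask → drop pipeline is idempotent on its own output except in
the contrived case where removing a column joins two sub-threshold
disagreement runs.

Locus dedup removes, from any pair of loci sharing at least one canonical
20-mer, the locus of smaller total ungapped length (ties: the
lexicographically later id), repeating until the retained loci are pairwise
disjoint. Repeat masking compares each sequence's k-mer coverage track
(mean multiplicity in the WGS read set of the k-mers covering each
position) against `elevation_factor` (5) times its median; "substantially
elevated" is not quantified by the source, so the factor is configurable.

The multiple alignment itself is delegated to MAFFT through an adapter when
the binary is on the PATH, with an internal gapless star alignment as a
fallback for substitution-only data and fixtures.

## Probe tiling

Probes of `probe_length` (120 bp — a standard capture-oligo length, chosen
here as a convention and configurable) start every
`round(probe_length / tiling_density)` bases; at the default 3.5× the step
is 34. The final probe is right-anchored at the sequence end so terminal
coverage has no gap; the step rounding and right anchoring are choices the
source does not constrain. Away from the ends, every position is covered
by `floor(density)` or `ceil(density)` probes. Probes crossing a masked or
N position are dropped and reported.

## The synthetic panel and what the tests mean

`simulate_panel()` generates, per locus, a root sequence with a conserved
core (`locus_length` 400 bp) and flanks (`flank_length` 400 bp each side);
each taxon's copy mutates flanks at `within_divergence` (0.10) and the core
at half that rate — conserved anchors with variable flanks. Copies are
embedded on random strands in random background (400 kb per taxon, spaced
~12 kb apart so the 10 kb candidate windows of neighbouring loci cannot
fuse). Repeat families (2 × 10 exact copies of 300 bp) are clustered in a
lead background zone away from the anchors, reflecting that the design
stage masks repeats precisely so that probe regions avoid them; the repeat
masking tests plant their own repeat inside a locus to exercise that path.
Transcript sets are the cores of the first two taxa.

`simulate_reads()` draws uniform fragments (mean 250 bp, sd 30),
sequences 150 bp from both ends, injects uniform per-base substitution
errors (default 1%), reads through into the adapter when the fragment is
short, and supports planted 50/50 two-allele sites.
`simulate_capture_reads()` restricts fragments to the planted locus windows
(±150 bp) at enrichment-scale coverage — default 600× read-base coverage,
the order of depth hybrid capture delivers and comfortably above the
study's 250× consensus gate — plus a 2% off-target background fraction.

The default study conditions (10 taxa × 20 loci, 10% divergence, 600×
capture, 100 decoy contigs) are what `run_recovery_study()` and the
acceptance script execute; the whole run takes a few minutes on one CPU.

The mutation model is substitution-only by default so truth alignments stay
positional and oracles exact. Real data differ in ways the generator does
not emulate: indels (the gapless layout would fragment around them),
structured sequencing-error profiles, allele-frequency skew, contamination,
uneven capture efficiency, and genuine gene-family paralogy. Passing tests
therefore demonstrate the pipeline's contracts and statistical behaviour
under its stated model, not performance on arbitrary real libraries.

## Known limitations

* Gapless everywhere: indel-bearing reads are not recruited, and the
  internal fallback aligner cannot open internal gaps (use the MAFFT
  adapter for real data).
* Exact k-mer counting only — no sketches; sized for desk-scale data.
* One consensus per locus and sample: allele-split clusters are not
  emitted separately; heterozygosity surfaces as ambiguity codes instead.
* The barcode module compares against a local reference FASTA; it
  implements the assignment rule, not a remote database search.
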