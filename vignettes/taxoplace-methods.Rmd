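---
title: "taxoplace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{taxoplace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxoplace)
```

## The model

`taxoplace` assigns each query genome a seven-rank taxonomy
(`d__;p__;c__;o__;f__;g__;s__`) relative to a fixed, rooted,
taxonomy-decorated reference tree. Three signals are combined, in a fixed
order of authority:

1. **ANI first, for species only.** If the query attaches inside or
   immediately beside a single genus clade, its fragment-based average
   nucleotide identity is computed against the representative genome of
   every species in that genus. Among references whose alignment fraction
   (AF) strictly exceeds the threshold, the highest-ANI reference is taken;
   the query receives that species iff its ANI is at or above the species'
   circumscription radius. A successful species assignment ends the
   decision: the RED machinery is never consulted (and conversely, a
   topology/RED classification never resolves the species rank).
2. **Topology.** Failing ANI, the query is grafted onto its attachment
   edge. The taxon labels on the root-to-attachment path fix the upper
   ranks; the labels below the attachment bound the lower ranks. The ranks
   in between form the *candidate window* — the possible "novel rank" of
   the query. A window of size one needs no further evidence.
3. **RED.** Larger windows are resolved by relative evolutionary
   divergence. RED is computed once for the reference tree
   (`red(n) = red(p) + (d/u)(1 - red(p))`, root pinned at 0, leaves at 1,
   `u` = mean path length from the parent to the leaves below `n`); the
   query's RED is the linear interpolation along its attachment edge at the
   placement's distal length (the pendant branch deliberately does not
   contribute, so the query is comparable to reference nodes whose RED also
   ignores it). The window rank whose median RED is nearest wins; exact
   ties go to the more inclusive rank, which deliberately under- rather
   than over-classifies.

The chosen novel rank r\* and everything below it stay empty; a
`"novel <rank>"` warning records it. Ranks between the deepest ancestor
label and r\* are inherited from the stacked labels of the single crown
node below the attachment — this is what lets a genome that is "the most
basal order of the sole class of a phylum" keep that phylum and class name
while remaining a novel order.

### The candidate window in detail

Let `A` be the deepest rank labeled on the root→attachment path. On the
child side of the attachment, collect the *crown labeled nodes* — labeled
nodes with no labeled ancestor inside that subtree.

* Several crowns carrying distinct taxa at their shallowest rank `s`: the
  query can belong to none of them, so the window is `(A, s]` (size one
  when `s = A + 1`: e.g. basal to several phyla of a domain means a novel
  phylum outright).
* A single crown whose label stack spans ranks `s..t`: the query may also
  split the stack, so the window is `(A, t + 1]`, capped at species. An
  attachment above a genus crown therefore has window {genus, species}.

Species never has a RED median (by design: species are ANI territory), so a
window containing species falls back, per the documented rule, to the most
inclusive window rank with a warning. In the {genus, species} case this
means: ANI already had its chance to call the query a (basal) species of
the genus; once ANI has refused, the RED route conservatively reports a
novel genus. A placement *inside* a species clade (possible with the naive
placer, which attaches to terminal edges) is treated as window {species}:
species membership was already refused by ANI, so the query is at worst a
novel species of its genus.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 16 | bases | exact-seed length for fragment mapping; 4^16 ≫ genome sizes, so random seed collisions are negligible |
| `fragment_len` | 3000 | bases | non-overlapping query fragments; the standard fragment size for fragment-based ANI |
| per-fragment identity floor | 0.8 | fraction | a fragment counts as aligned only at ≥80% identity, preventing spurious low-identity fragments from dragging the mean |
| `af_threshold` | 0.65 | fraction | **strict** (`>`): AF at exactly 0.65 fails, matching the stated ">65%" rule; computed on the query side |
| `default_radius` | 95 | % ANI | species circumscription radius when a species is absent from the radii table; per-species radii override it; comparison is **inclusive** (`>=`), matching "within the radius" |
| `min_completeness` | 50 | % | QC floor, inclusive |
| `max_contamination` | 10 | % | QC ceiling, inclusive |

QC is advisory by default — failing genomes are flagged, not dropped —
because the thresholds are a recommendation about reliability, not a hard
precondition of the algorithm; `strict_qc = TRUE` excludes failures (they
still get a summary row, with an empty classification, so batch accounting
stays exact).

## Numerical choices

* RED: the recursion uses exact postorder accumulators; `d = 0` or a
  degenerate `u = 0` inherit the parent's RED. Because `u >= d` by
  construction, RED is monotone root→leaf on every tree, and since it
  depends only on length *ratios* it is invariant under global rescaling of
  branch lengths. Both properties are asserted against a brute-force
  path-enumeration oracle in the tests (tolerance 1e-10 over 1000 random
  trees).
* Nearest-median comparisons use an absolute tolerance of 1e-12 to detect
  ties; the tie rule (more inclusive rank) is therefore stable under
  floating-point noise.
* Newick branch lengths are written with 15 significant digits, so a
  read/write round trip is lossless well past the 10 significant digits
  the io contract demands; a second round trip is byte-identical.
* Fragmenting: trailing partial fragments are dropped (so a self-comparison
  is exactly ANI 100 / AF 1 at any genome length); only a genome shorter
  than one fragment yields a single truncated fragment, flagged, whose
  identity denominator is its actual length.
* Ties elsewhere are resolved deterministically and loudly: equal naive
  placements go to the lexicographically smallest leaf, equal-ANI species
  to the lexicographically smallest name, equal jplace likelihood weights
  to the lowest edge number — each with a warning.

## The synthetic world

`gen_reference()` builds a balanced, rank-stratified, **ultrametric** tree:
crown depths are fixed per rank (phylum 0.30, class 0.45, order 0.60,
family 0.72, genus 0.85, species 0.98, leaves 1.0; phyla join pairwise
through unlabeled nodes at 0.15 when there are at least four). On an
ultrametric tree RED equals relative depth exactly, so the per-rank RED
medians are known in closed form and separated by at least 0.08 — the
margin the RED resolver is tested against. This is a deliberate deviation
from a random birth–death shape: the topology carries no randomness (the
sequences carry all of it), and every truth value the query generator
writes can be computed arithmetically rather than by running the
classifier.

Sequences evolve along the tree under uniform i.i.d. substitution (any of
the 3 alternative bases, or 19 alternative amino acids, equiprobable), so a
direct mutation at rate `d` has expected identity exactly `1 - d`; with
50 kb genomes the binomial standard error of fragment ANI is ≈0.1%, well
inside the ±0.5 calibration band the tests enforce. The default genome
substitution scale (0.25 per unit branch length) puts congeneric species at
~92–93% ANI — outside a 95% radius — and conspecific genomes within it.

All randomness flows from one master seed through named substreams (one per
node, genome, marker and decision), so regenerating with the same seed is
byte-identical and adding a genome never perturbs the others.

Query modes mirror the canonical scenarios: `known_species` (2% divergence
from a representative → ANI assignment), `novel_species` (8% → inside the
genus, outside the radius), `novel_genus` (evolved from a family crown,
attached above a genus), `novel_phylum` (attached between phyla),
`basal_ambiguous` (attached part-way along an inter-rank edge, forcing the
RED rule; the truth rank is the nearest-median rank computed from the
generator's own depth table). At these fixed depths an above-crown
placement is always nearest the most inclusive window median, so the
"ambiguous" mode resolves deterministically — it exercises the RED code
path, not genuine uncertainty.

**What a green test does not establish.** The fixtures have no indels, no
rate heterogeneity, no gene-order or content variation, no assembly or
sequencing artifacts, balanced taxon sampling, and perfectly consistent
decoration. Recovery of 100/100 fixture queries says the decision engine
implements its rules exactly; it does not reproduce, and cannot be compared
with, benchmark agreement numbers obtained on real reference releases with
curated taxonomies.

## Scope and known limitations

* Gene calling, HMM marker search and likelihood placement are external:
  the package consumes their standard outputs (hit tables with aligned
  rows; jplace). The built-in placer is an alignment-distance fallback that
  attaches to terminal edges only — adequate for species-level queries and
  for testing, not a pplacer substitute.
* One reference package (one domain's tree) per run; `assign_domain()`
  implements the two-proportion rule and is available when hit counts for
  both marker sets exist, but the pipeline does not juggle two trees in a
  single invocation.
* ANI is one-directional (query → reference) with ungapped extension;
  indel-rich pairs lose alignment fraction, which errs on the conservative
  (novel species) side.
* Novel taxa are reported as empty rank suffixes plus warnings, never as
  auto-generated placeholder names: naming is curation, not classification.
* No placement uncertainty, no multi-placement consensus, no bootstrap
  support: like the tool it models, only topology, RED and ANI speak.
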