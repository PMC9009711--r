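---
title: "Evaluating phylogenetic profiling for eukaryotic interaction prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating phylogenetic profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Phylogenetic profiling predicts functional links between proteins from the
correlated presence and absence of their orthologous groups (OGs) across a
set of genomes: subunits of one complex tend to be gained and lost together,
so similar profiles suggest interaction. In eukaryotes the performance of
this simple idea varies widely between studies, and much of the variance
comes not from the profiling method itself but from *meta-parameter* choices
that are often implicit: which genomes go into the matrix, which OGs are
profiled, and which reference interactome defines truth. `phyloprof`
implements the full evaluation pipeline for these choices — profile
construction, Dollo-parsimony OG classification, benchmark construction from
BioGRID-style interaction tables, cosine-similarity scoring with ROC/AUC
evaluation, the genome- and OG-selection procedures, and a GO-enrichment
contrast between reference interactomes — together with a synthetic-world
generator that provides ground truth for every stage.

## Core model and statistics

**Profiles.** The central object is a binary OG-by-species matrix: entry
$(g, s) = 1$ when OG $g$ has at least one member gene in species $s$. Gene
multiplicity is deliberately collapsed; only presence carries signal here.

**Similarity.** Two profiles $a, b$ are compared by the cosine distance
$d(a,b) = 1 - a \cdot b / (\lVert a\rVert\,\lVert b\rVert)$, which for
binary vectors lies in $[0,1]$ and equals 1 exactly when the supports are
disjoint. The distance is undefined on an all-absent profile, so rows that
become all-zero under a species subset are dropped from scoring and counted;
the same rule removes pairs (not failures, exclusions) during evaluation.
Candidate pairs are scored as $1 - d$; any strictly monotone transform
would give the same AUC, since the evaluation is rank-based.

**Evaluation.** Positive pairs come from an evidence-filtered reference
interactome (physical interactions supported by at least five independent
publications); negatives are pairs of well-studied proteins — each seen
with five or more publications in *some* interaction — that were never
reported together at any evidence level. The conservative "never reported"
rule minimizes false negatives in the negative set. AUC is computed exactly
as the Mann–Whitney statistic with half-credit for ties,
$(\#\{p > n\} + \tfrac12\#\{p = n\}) / (n_p n_n)$, and the tie-aware ROC
curve advances diagonally through tie groups so that its trapezoidal area
equals the rank statistic to machine precision. No interpolation is ever
used.

**Ancestral content.** Each OG is reconstructed under Dollo parsimony: a
single gain at the most recent common ancestor of the present species, with
losses minimized — one loss per maximal all-absent subtree below the gain.
An OG is assigned to the last eukaryotic common ancestor (LECA) when its
present species cover at least three supergroups spanning both domains
(Amorphae and Diaphoretickes); otherwise it is post-LECA. Classification
uses the supergroup-spread rule directly; the gain node and loss count are
reported descriptively. Multifurcating trees are supported, each child edge
counted independently.

**Genome quality.** Two per-genome metrics: externally supplied BUSCO
absence counts (the package ingests the counts; running BUSCO is out of
scope), and the illogical-absence (IA) statistic. For the strongest
interacting OG pairs — by default the lowest-distance decile of the positive
pairs, a relative cut that is robust to benchmark size — each species is
classified per pair as co-presence, co-absence, or illogical absence
(exactly one partner present). The IA ratio is
$\mathrm{IA} / (\mathrm{co\text{-}absence} + \mathrm{IA})$, reported as
missing when a genome has no absences at all, never as 0, to avoid ranking
artifacts.

## Selection procedures

* **Quality:** the $k$ genomes with fewest (best) or most (worst) BUSCO
  absences; ties break lexicographically; the reference-interactome species
  is excluded (its IA count is 0 by construction).
* **Diversity:** all species pairs are sorted by cosine distance
  (descending for the diverse set, ascending for similar); the set is
  seeded with the extreme pair and candidates are admitted only if their
  distance to *every* member satisfies the threshold (defaults 0.38
  diverse / 0.58 similar, the all-members rule). When a threshold cannot
  reach $k$ members the procedure either errors with the size reached or,
  on request, relaxes the threshold in steps of 0.01.
* **Random backdrops:** 1000 random genome subsets of size 50, and 1000
  random 63% subsets of the LECA OGs, both seed-reproducible. The analysis
  scripts and tests use 200-set backdrops to keep runs short; the quantile
  estimates are indistinguishable at that size for the comparisons made.
* **Influence:** leave-one-out deltas
  $\Delta_s = \mathrm{AUC}(\text{without } s) - \mathrm{AUC}(\text{all})$;
  the $k$ most negative deltas are the advantageous genomes, the $k$ most
  positive the disadvantageous ones.

Experiments 1–3 evaluate on the LECA OG profiles (the "initial set"), the
OG-selection experiment compares the LECA / post-LECA / unfiltered sets,
and the interactome experiment contrasts benchmarks on the full observed
matrix, so that each experiment varies exactly one choice.

## Enrichment

The reference-choice experiment asks *what* the weaker reference is missing:
OGs interacting only under the full reference (sample set) are tested
against OGs interacting under both references (population set). Because an
OG contains several genes, one gene per OG is drawn uniformly and the
contrast recomputed ten times. Per GO term the fold score is
$(n/m)/(k/q)$ — sample overlap proportion over population proportion — and
significance uses a one-sided hypergeometric over-representation test with
the union of the sampled sample and population genes as background (the two
OG sets are disjoint, so a population-only background could not even
support the observed overlap; both choices are available). Terms need
overlap $n \ge 3$ and $p < 0.01$; no multiple-testing correction is applied
by default, matching the raw cut the pipeline is calibrated against, and a
Benjamini–Hochberg option exists. GO ancestry is *not* propagated —
annotations are used as given — which is a documented limitation.

## The synthetic world

No public accessions accompany the study design this package implements, so
every analysis is exercised on synthetic worlds with known ground truth.
The generator is a first-class, tested module, and its defaults define the
study conditions used throughout the tests and the acceptance script:

* **Tree:** 80 species, random rooted binary topology whose first split
  separates the two domains, leaves partitioned into 8 monophyletic
  supergroups (4 per domain). Branch lengths are not used: loss is
  per-branch, reflecting that the analyses never consume lengths.
* **Modules:** 40 co-evolving modules of 8 OGs each, plus 100 singleton
  OGs. Eight members is the scale of well-known repeatedly-lost complexes,
  and it makes a fully dropped module detectable in the enrichment at the
  $n \ge 3$, $p < 0.01$ cut (a module whose eight sampled genes all land in
  the sample half of a balanced universe reaches
  $p \approx 0.5^8 < 0.01$). Two genes per OG exercise the resampling.
* **Loss:** per-module branch loss rates drawn from $U(0.03, 0.15)$ —
  heterogeneous rates are what make "the modules a lossy reference retains
  are the rarely-lost ones" meaningful. On every branch a module draws a
  loss indicator; each member copies it with probability $\rho = 0.9$ and
  redraws independently otherwise; a loss silences the whole subtree
  (single gain, no regain). Loss probability on deep branches (child clade
  $\ge 25\%$ of species) is scaled by 0.2: whole ancient mega-clades rarely
  lose a complex outright, and without this damping a material fraction of
  ancestral OGs would vanish from an entire domain, violating the intended
  LECA composition of the world.
* **Lineage innovations:** 30% of modules (and of singletons) are
  post-LECA. Their origins are drawn from the ancestors of the designated
  reference species — a reference interactome can only contain families
  with reference-genome members, so the innovations that reach the
  benchmark are the ones on the reference path — and each member OG draws
  its own origin along that path, because complexes accrete subunits over
  time. Post-LECA loss rates are scaled by 0.25, reflecting the lower loss
  observed for lineage-specific families; their profiles are accordingly
  information-poor. Origin clades span 8–32 leaves so no post-LECA module
  is degenerate.
* **Oversplitting:** 20% of ancestral-module members are observed as an
  artifactually lineage-restricted fragment — the profile truncated to an
  arbitrary clade on the reference path — emulating orthology
  oversplitting. These OGs classify as post-LECA while still interacting
  with their ancestral partners, which is precisely what drags the
  unfiltered ("all OGs") evaluation below the LECA-only one.
* **Noise:** 10 genomes (never the reference) receive false absences:
  each present entry flips to absent independently with probability 0.3.
  BUSCO absence counts are drawn per species as
  $\mathrm{Bin}(303,\; 0.02 + 0.6\,\varepsilon_s)$, tying the external
  quality metric to the injected corruption.
* **Interactomes:** true positives are all between-OG gene pairs inside
  retained modules. The full reference retains every module; the depleted
  ("yeast-like") reference is the species retaining the fewest module OGs
  and keeps only the top half of modules by its own retention — dropping
  the most-lost modules, as a lossy lineage does. Well-studied pairs draw
  5–20 PubMed ids; 10% of true pairs are under-studied (1–4 ids) and are
  lost to the evidence filter; noise pairs (30% of the true count) connect
  random non-module genes at 1–4 ids. Negatives then emerge from the
  never-reported rule rather than by construction fiat. GO annotations
  give each module one term covering all member genes, plus 30 random
  background terms.

With these conditions the synthetic analyses land remarkably close to the
qualitative structure the method shows on real data: the evidence filter is
worth roughly 0.18 AUC, the depleted reference loses 0.05–0.08, LECA-only
evaluation beats the unfiltered OG set which beats post-LECA-only, the
interacting LECA profiles carry ~0.9 bits of entropy against ~0.5 for
post-LECA ones, and the advantageous/disadvantageous leave-one-out sets
bracket the random backdrop.

### What the generator does not emulate

Real proteomes bring correlated annotation error (false absences cluster in
genomic regions and gene families, not independently per entry),
non-module interactions (regulatory, transient), alias ambiguity in gene
symbols, horizontal transfer and endosymbiotic gene flow, and taxon
sampling that is anything but uniform. Passing tests on these worlds
demonstrates the pipeline's correctness and the direction of each
meta-parameter effect under the stated model — not effect sizes on real
data.

One structural consequence deserves emphasis: with independent per-entry
false absences at rate 0.3 confined to 10 of 80 genomes, the rank-based
AUC barely moves (the noise shifts all similarities roughly equally, and
ranks respond only to churn at the positive/negative boundary). The
quality-selection and leave-one-out analyses therefore separate *weakly*
on these worlds — the selections are computed and reported, but a
noisiest-50 set that is 80% clean genomes does not fall outside a random
backdrop whose spread is set by module-level co-movement. On real data the
worst genomes are degraded wholesale, not 10-of-50, which is why the
published contrast is visible there.

## Numerical choices and degenerate inputs

* Ties in every ranking (quality counts, pair distances, influence deltas,
  greedy admission order) break lexicographically on identifiers, making
  all selections reproducible.
* Cosine similarity is clamped to $[0,1]$ against floating-point drift;
  the ROC integration is exact, and equality with the rank AUC is asserted
  to $10^{-12}$ in the tests.
* All-absent profiles: error in `cosine_distance`; dropped-with-count in
  every caller (matrix subsetting, pair scoring, benchmark evaluation).
* Duplicate identifiers, missing species, negative counts, impossible
  hypergeometric configurations: immediate errors naming the offender.
* Seeds are explicit everywhere (`withr::with_seed`); no function leaves a
  perturbed global RNG state, and rerunning any experiment with one
  configuration is byte-identical.

## Problem sizes

The bundled analyses and tests run the default 80-species world with
200-set random backdrops, ten resampling repeats for enrichment, and ten
world replicates for the ordering checks; the full pipeline completes in
well under a minute per world on one core. The procedures themselves scale
linearly in pairs and species and have been written matrix-wise throughout,
so the 1000-set backdrops of a full-scale study are a parameter change
(`n_random`), not a code change.

## Known limitations

* The LECA criteria implement the supergroup-spread rule only; any
  stricter inclusion criteria used upstream of a real orthology run are
  the data producer's responsibility.
* The negative-set "never reported together" rule is conservative by
  design and cannot be balanced or down-sampled except explicitly
  (`max_negatives`), because the original study does not state a size.
* Gene identifiers are taken verbatim (case preserved, no alias
  resolution).
* GO enrichment treats annotations as flat labels; no graph reasoning.
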