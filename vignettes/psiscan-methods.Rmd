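---
title: "psiscan: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{psiscan: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiscan)
```

## The measurement model

Bisulfite forms an adduct with pseudouridine (Ψ) that reverse transcriptase
cannot read through cleanly: it skips the base, so the cDNA carries a
single-nucleotide deletion at the modified uridine. Sequencing both a
treated and an untreated half of the same RNA sample and piling up per-base
counts turns Ψ detection into a per-position two-sample count problem. For
depth $d$ and deletion count $k$ the deletion fraction $f = k/d$ is, to
first order, the fraction of transcript molecules modified at that site
(the stoichiometry). The model assumptions worth stating explicitly:

* deletions at a site are independent across reads, so $k \sim
  \mathrm{Binomial}(d, f)$ at fixed depth;
* the untreated half shares everything with the treated half except the
  chemistry, so its deletion rate is the site's technical noise floor;
* depth counts every read spanning the position *including* reads that
  carry the deletion — this is the pileup convention of the upstream
  tools, and it is what makes $k/d$ a proportion rather than an odds.

The assay is unstranded: a deletion pile-up tells you a uridine was
modified on *some* strand. `psiscan` therefore treats a genomic T as a
candidate U on the plus strand and a genomic A as a candidate U on the
minus strand, and defers strand-of-origin to annotation overlap. That
choice is not a shortcut — it is what lets the identical call set expose
antisense transcription.

## Calling filters and their defaults

Isolate mode: depth ≥ 20 in both halves, treated deletion count ≥ 5,
treated fraction ≥ 0.05, untreated fraction < 0.01 (both inequalities on
the fractions are deliberate: ≥ on the signal side, strict < on the noise
side, so a site sitting exactly on the noise cutoff is rejected). The
reported Ψ proportion is the treated fraction itself, because the untreated
filter has already bounded the noise below a tenth of the minimum signal.

Microbiome mode keeps depth ≥ 20 and count ≥ 5 but replaces the untreated
cap — strain-level indel polymorphism makes a fixed 1% cap untenable in a
community — with three relative filters: treated fraction ≥ 0.02, treated ≥
2 × untreated, and a one-sided Fisher exact p < 0.01 on the 2×2 table of
(deleted, non-deleted) × (treated, untreated). The Ψ proportion becomes the
Δ deletion fraction, floored at 0 since negative stoichiometry is
meaningless. Two conventions needed fixing: an untreated fraction of
exactly 0 passes the fold filter (an infinite fold exceeds any threshold),
and the Fisher test is one-sided toward treated enrichment because the
chemistry predicts the direction; a two-sided test would pay for power
against an alternative that cannot occur.

High confidence requires the identical (reference, position, strand) in at
least two treated libraries — replicates or different conditions both
count, untreated libraries never do (they carry no Ψ signal). Calls inside
runs of ≥ 2 consecutive uridines are flagged: aligners left-align
deletions, so within a run the exact modified position is unresolvable.
The standalone `flag_homopolymer_ambiguity()` repositions to the leftmost U
of the run to make that convention explicit; the callers attach the flag
without moving coordinates, since their input is already left-aligned.

## Gene-level quantities

Ψ-strength is the sum of site fractions within one RNA — a load, not an
average, so a transcript with three half-modified sites scores 1.5. PUS
assignment and stress differentials both ask for a Ψ-strength difference ≥
0.05 *in every replicate pair*, replicates paired by index; the comparison
is taken over the union of sites seen in either genotype/condition, with an
absent site contributing 0 — otherwise a site abolished in the mutant would
silently drop out of the very comparison designed to find it. The stress
contrast additionally flags (rather than removes) candidates whose control
strength reaches half the cutoff: these near-miss controls are where manual
review is worth the time.

TPM uses a pseudocount of 1 per gene ((count+1)/length, normalised to
$10^6$); in microbiome mode genes with fewer than 5 reads in *all* samples
are dropped before normalisation, so the denominators reflect only genes
the community data can actually quantify.

## Motifs and antisense candidates

Motif extraction uses a fixed 5-mer window (2 nt each side, Ψ central,
minus-strand sites reverse-complemented first) because the dominant
bacterial Ψ motifs are 5-mers with the modified U in the middle; shorter
consensus motifs (GUUC, UCC, UUGC) fall out of the modal consensus
summariser over significant k-mers rather than out of a narrower window.
The site filter (fraction strictly above the threshold, then motifs with ≥
5 retained sites) defaults its threshold to the *median fraction of the
input*, not a constant: the published 6% figure is a dataset statistic and
should be recomputed per dataset, with an override for users who want the
fixed value. Genotype contrasts use the two-sided Wilcoxon rank-sum test —
exact when both groups have ≤ 10 tie-free observations, the tie-corrected
normal approximation otherwise — with Benjamini–Hochberg adjustment across
the motifs of one contrast.

Antisense candidates are high-confidence calls overlapping a gene on the
opposite strand; a call under genes on both strands is discarded as
ambiguous. "Downstream" is always in the antisense transcript's direction.
Promoter and terminator predictions come from external tools and are
ingested as score tables; windows qualify when they overlap the 200 bp
upstream (promoter) or 150 bp downstream (terminator) search region with
probability ≥ 0.9, the highest-scoring window wins, and the predicted TSS
is taken as the promoter window's edge nearest the Ψ site. The sRNA span
runs inclusively from the TSS to the terminator-window midpoint; an
even-length window floors the midpoint on the plus strand and rounds up on
the minus strand — the asymmetric rounding is what makes mirrored inputs
give identical lengths.

## The synthetic-data generator

`sim_config()` defines the simulated study conditions, and the generator
works directly in pileup space: the method consumes pileups, so simulating
reads and re-aligning them would add aligner behaviour without testing any
more of the method. Untreated counts are Binomial(depth, background);
treated counts at planted sites are Binomial(depth, background +
stoichiometry); strain-heterogeneity positions add a treatment-independent
deletion rate to *both* halves, because strain indels are genomic — this is
precisely the confounder the microbiome fold and Fisher filters exist to
remove, and simulating it on one side only would make those filters look
better than they are.

Defaults, chosen once: 100 kb reference at 50% GC (enteric-bacteria-like
composition, which is also what makes the null deletion-ratio diagnostic
symmetric); background deletion rate 0.001, a tenth of the isolate noise
cap; planted stoichiometries uniform on [0.05, 0.6], spanning the calling
floor up to the strong sites seen in deep libraries; 2 replicates. Mean
depth defaults to 300×. That last choice deserves its reasoning: the
isolate filter demands an untreated fraction strictly below 1%, and at
100× a *single* background deletion (rate 0.001) already sits at the cap,
so ~9.5% of genuinely modified sites would be rejected by noise alone —
at 300× the cap tolerates two background deletions and the filter operates
in the regime it was designed for (real libraries over expressed bacterial
genes are deeper still). The diagnostic-ratio simulations use 100× because
there the quantity of interest is aggregate frequency, not per-site
calling.

What the generator does *not* emulate: sequence-context-dependent RT
errors, alignment and realignment artifacts, mismatches and insertions,
coverage autocorrelation along transcripts, and expression-level variation
between genes. Passing tests therefore demonstrate the statistical
machinery under the stated generative model — they do not certify
performance on real libraries, where the untreated half is the only honest
estimate of the local noise.

## Numerical and degenerate-input choices

* Deletion fraction is undefined at depth 0 and raises an error; callers
  pre-filter instead (a position missing from the untreated table counts as
  depth 0 and simply fails the depth filter).
* A base class with zero aggregate depth reports a missing ratio, never 0;
  pairwise ratios against a zero-frequency base are skipped rather than
  propagated as infinities.
* Fisher p-values come from the exact hypergeometric tail
  (`stats::phyper`), verified in the test suite against brute-force
  enumeration over every 2×2 table with total ≤ 60 (agreement ~1e-14).
* Exact Wilcoxon p-values are verified against enumeration of all
  $\binom{n_1+n_2}{n_1}$ rank splits for group sizes ≤ 6.
* All internal coordinates are 1-based inclusive; BED export converts to
  0-based half-open at the boundary and every writer states its convention
  in a header comment.
* Aggregation merges by exact (reference, position, strand); homopolymer
  equivalence is flagged but never used to merge distinct coordinates.

Problem sizes in the shipped tests were picked so the whole suite runs in
well under a minute of simulation time: 100 kb genomes with 1,000 planted
sites for the end-to-end and diagnostic checks, 5–20 kb genomes elsewhere.

## Known limitations

* Stoichiometry is bounded by the deletion-induction efficiency of the
  chemistry; the package reports deletion fractions as proportions and
  leaves any efficiency correction to the user.
* In U homopolymers the site is localised only to the run.
* Microbiome mode applies a fixed p cutoff per site, not a
  multiple-testing-corrected one; with millions of tested positions the
  fold-change and count filters, not the p-value, carry most of the
  specificity.
* PUS assignment is by elimination (signal lost in a knockout) and cannot
  distinguish direct from indirect effects.
* Promoter/terminator evidence is only as good as the external predictors
  whose scores are ingested.
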