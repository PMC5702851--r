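---
title: "Calling and comparing A-to-I RNA editing with editomer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing A-to-I RNA editing with editomer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editomer)
library(dplyr)
```

## The problem and the model

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA; inosine
base-pairs like guanosine, so an edited position shows an A>G mismatch
between RNA reads and the genomic DNA (T>C when the gene lies on the minus
strand of the reference). Distinguishing editing from everything else that
produces RNA-DNA mismatches — germline variants, sequencing error,
misalignment over repeats and homopolymers — is the core inference problem.
`editomer` treats it as a filtering cascade followed by a cluster test:

* **Evidence thresholds.** A pileup column becomes a candidate when read
  coverage is at least 10, at least 2 reads support the alternative allele,
  and the alternative-allele fraction is at least 5%, counting only
  non-duplicate reads with mapping quality of 20 or more. The first two
  cutoffs are the classical RNA-variant thresholds; the frequency floor
  exists because a fixed 2-read count rule otherwise admits paired
  sequencing errors wherever coverage is high (2 of 150 reads is far more
  consistent with error at typical per-base error rates than with editing).
  Base quality is deliberately not used by default (`min_baseq = 0`): the
  gate is on mapping quality, and a base-quality knob is exposed for
  libraries where it matters.
* **Filtration cascade.** Five pure positional predicates remove candidates
  at DNA-variant positions (anything the pooled DNA sample supports at
  fraction >= 0.1, >= 2 reads, depth >= 10 — aggressive on purpose, any DNA
  evidence disqualifies a site), known SNPs, intergenic positions (gene
  body = transcript span including introns, which remain editing
  territory), reference homopolymer runs longer than 5 nt, and simple
  repeat intervals. Because each predicate depends only on the position,
  the surviving set is independent of the order of application; the full
  trail of failed filters is kept per candidate for auditability.
* **Cluster calling.** ADAR editing is hyper-local: many same-type sites
  within a short stretch. Surviving candidates of the same mismatch type
  are single-linkage clustered at <= 200 bp; clusters of >= 2 sites are
  called, and a lone site is only rescued when its alt fraction reaches
  0.2. All three parameters are exposed. This is a deliberately auditable
  stand-in for published cluster-based callers whose internals are not
  specified; it captures the "same editing type, close together" signal
  without a learned model.

## Quantifying and comparing editing

Per-sample calls are unioned into a master list keyed by (chrom, pos, ref,
alt) — a site called in one sample is re-evaluated in all of them. The
editing degree of site *s* in sample *j* is `alt_reads / total_reads` from
that sample's filtered pileup; samples with coverage below
`recall_min_depth = 5` are treated as missing rather than as zero (the
choice is configurable; with degrees that are ratios, low-coverage zeros
would otherwise drag group means). Group means average the available
replicates. Dose arms of the same drug can be merged simply by mapping both
sets of samples to one group.

A site is **high variation** when the group-mean degree changes by more
than 0.15 against control in *every* treatment, **low variation** when it
stays below 0.05 in every treatment. Change is treatment minus control on
group means; direction is `up`/`down` when all deltas agree in sign. Sites
that exceed the threshold with opposite signs in different arms form an
explicit `discordant` class — they are high-variation but belong to neither
the up nor the down tally, so `n_up + n_down + n_discordant = n_high` holds
by construction. Thresholds are fixed cutoffs, not hypothesis tests; that
is intentional and mirrors how such groups are defined in practice, and the
classifier is monotone in its thresholds (raising the high threshold can
only remove sites).

Region annotation uses precedence CDS > UTR > intron within a transcript
and labels disagreements between overlapping transcripts `conflicting`.
Codon consequences rebuild the affected codon on the coding strand
(reverse-complementing on minus-strand genes) and translate with the
standard genetic code; CDS lengths must be multiples of 3 or annotation
errors are raised rather than guessed around.

## Sequence context statistics

`two_sample_logo()` compares flanking composition between two site sets.
Flanks are oriented so the edited base always reads as the canonical
adenosine (minus-strand sites are reverse-complemented), the centre column
is excluded, and every (position, nucleotide) cell gets Fisher's exact test
on the 2x2 table of counts. Fisher was chosen over the t-test/binomial
variants of classical two-sample-logo tools for determinism and small-set
robustness; a two-proportion test is available via `test = "binomial"`. No
multiple-testing correction is applied by default — the display convention
for such logos is a raw per-cell threshold (alpha = 0.05) — but Bonferroni
is one flag away. With exact tests on discrete counts the realised false
positive rate under label shuffling sits at or slightly below alpha; the
test suite checks exactly that. The flank half-width defaults to W = 10,
an unstated-but-conventional window size.

## Expression and correlation

FPKM follows the standard formula
`fragments * 1e3 * 1e6 / (transcript_length * total_fragments)`. Fold
changes are computed on group-mean FPKM with **no pseudocount**: a
recomputation of the bundled FPKM table confirms the printed log2 fold
changes only without one (a 0.02-FPKM control value yielding -6.53 rules a
pseudocount out), so zero-control genes get infinite fold changes and are
excluded from correlation rather than smoothed. The normalized matrix for
visualisation does use `log2(x + 1)` followed by per-gene centring.
Regulation calls require the 1.5-fold change in *both* drug arms.

The editing-expression correlation pairs each high-variation site's degree
change with its gene's log2 fold change for the same treatment; the point
estimate and two-sided p come from the standard Pearson test and the 95%
interval from the Fisher z transform, `tanh(atanh(r) ± 1.96 / sqrt(n - 3))`.
With fewer than 3 usable pairs, or zero variance on either axis, the
function refuses rather than returns a number.

## miRNA rebinding

The miRNA scanner is intentionally a simplified model, and is documented as
such: a hit needs 7 consecutive Watson-Crick pairs between miRNA seed
positions 2-8 and the mRNA-sense window, extended gap-free in both
directions scoring +2 per Watson-Crick pair and +1 per G:U wobble. No
thermodynamics, no accessibility. Its evidential output — which base pair
the edited position forms with which miRNA, before and after editing — is
the part that gain/loss classification actually needs. "A 50-bp window
around the site" is read as a *total* width of 50 (25 up, 24 down); the
per-flank alternative is available through the `width` argument since the
phrase is genuinely ambiguous.

## What the synthetic editome emulates — and what it does not

`sim_config()` defaults describe the study design the pipeline targets:
nine RNA samples grouped control 3 / gentamicin 4 / neomycin 2 (the 3/4/2
split is an assumption recorded in the config, since only the total of nine
is fixed), one pooled DNA sample, clustered A>G editing placed mostly in
3'UTRs, germline het/hom SNP decoys, homopolymer and simple-repeat decoys
carrying RNA-only mismatches, and gene abundances with 1.5-2x fold changes
in a subset of genes. Editing rates default to 0.35 in control and
0.62/0.60 under treatment — a ~26-27 percentage-point shift, the magnitude
the variation classifier is designed to detect. Sequencing parameters
default to 100-bp reads, mean RNA coverage 50, DNA coverage 30, per-base
error 0.002, 5% of reads at low mapping quality, and 2% duplicated
fragments. Genome sizing (2 chromosomes x 50 kb, 12 genes x 3 exons of
500 bp) keeps a full nine-sample run near half a minute; deeper-coverage
scenarios in the tests shrink the genome instead of the depth.

Simplifications to know about:

* Reads are emitted **pre-aligned and wholly within single exons** —
  match-only alignments cannot represent junction reads, so alignment
  artefacts and splice-aware behaviour are out of scope, and simulated
  coverage decays within a read length of exon edges. Planted sites are
  therefore placed in exon cores, where they experience the configured
  nominal depth.
* Paired-end geometry is reduced to single-end reads with a stored mate
  position (sufficient for coordinate-based duplicate marking).
* The error model is uniform substitution; no indels, no quality-score
  structure, no sequencer-specific error profiles.

Passing tests on this generator therefore demonstrate correctness of the
counting, filtering, classification and statistics — not robustness to
alignment artefacts or library-specific error structure in real data.

## Numerical and degenerate-input choices

* Coordinates are 1-based fully closed on the reference strand everywhere
  inside the package; BED's 0-based half-open intervals are converted at
  the I/O boundary only.
* Alt-allele ties at a column break deterministically by base order
  A < C < G < T; duplicate-marking survivors are chosen by base-quality
  sum, then read name, so results never depend on input order.
* `N` reference or read bases are excluded from pileup counts and
  candidate positions.
* Degrees, group means and frequencies are plain ratios in [0, 1];
  reports that print percentages multiply by 100 at the formatting step
  (one decimal for degree tables, two for FDR percentages).
* Empty inputs return empty, correctly-typed tibbles; genuinely undefined
  quantities (FDR with zero assessed sites, correlation on constant input)
  raise errors instead of NA-propagating.

## Problem sizes used by the test and acceptance runs

The bundled suites use: the default 2 x 50 kb genome for the end-to-end
recall/precision run (nine samples, ~80k RNA reads); a 1 x 30 kb genome at
coverage 200 for the variation-direction property (18 planted sites); 200
sequences per set for logo detection with 100 label shuffles for null
calibration; and 200 replicates of n = 500 for correlation CI coverage.
These sizes were chosen so each property is measured with comfortable
statistical margin while a full run stays in the tens of seconds.

## Known limitations

* The cluster caller is a transparent reimplementation of the
  "same type, close together" idea, not a reproduction of any published
  caller's internals; parameterisations differ and counts on real data
  will too.
* One GTF is the single annotation source; `conflicting` region labels
  capture transcript-level disagreement within it, not disagreement
  between databases.
* No statistical test accompanies the 15%/5% variation thresholds, by
  design.
* The miRNA scanner's scores are not comparable to thermodynamic
  predictors; only gain/loss/retention status and the pairing identity at
  the edited base should be interpreted.
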