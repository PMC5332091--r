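---
title: "Methods: genome-wide HD-Zip family characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide HD-Zip family characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model of the analysis

`hdzipr` re-implements, as tested and reusable functions, the complete
genome-wide characterization workflow for the plant HD-Zip
transcription-factor family: identification of dual-domain (homeodomain +
leucine zipper) members in a proteome, classification into subfamilies
I--IV, exon--intron structure and conserved-motif analysis, tandem and
segmental duplication calling, promoter cis-element enrichment, and
expression/qPCR statistics. Every stage can be exercised end-to-end on
synthetic genomes with planted ground truth, which is how the package
validates itself.

The thresholds used throughout are the family-analysis conventions this
workflow standardizes on: domain E-value < 0.01; FPKM > 1 for "expressed";
absolute fold change > 2 for "changed"; tandem duplicates within 50 kb;
segmental duplicates supported by chained alignments of the 100-kb
flanking windows with per-block length > 200 bp and identity > 85%;
1500-bp promoters upstream of the translation start; 1000 bootstrap
replicates; Duncan's multiple range test at P < 0.05 with n = 3. All of
them are exposed in `pipeline_config()` and echoed into the run manifest.

# Identification: profiles, empirical E-values, and the low-score guard

Full profile-HMM search is replaced by ungapped position-specific scoring
matrices (`build_profile()`, log-odds in bits with a pseudocount) scanned
over every window (`scan_profile()`). Significance is an empirical
shuffle null: the query is shuffled `null_shuffles` times (composition
preserved) and

\[
E = \mathrm{db} \cdot \frac{1 + \#\{\text{null max-scores} \ge \text{observed}\}}{\text{null\_shuffles} + 1}.
\]

This choice is deliberate: it is desk-scale, dependency-free, and on
sequences whose domains are embedded without insertions it ranks hits the
same way a profile HMM would. Two consequences matter in practice:

* **Granularity.** The smallest attainable E-value is
  `db / (null_shuffles + 1)`. The default (199 shuffles, per-query scale
  `db = 1`) puts the floor at 0.005, below the 0.01 threshold. A
  database-scaled threshold would need proportionally more shuffles.
* **Floor ties.** A sequence can tie the floor even when its best window
  score is deeply negative (its own shuffles all score worse). Retention
  in `identify_family()` therefore also requires a positive log-odds
  score (`min_bits = 0`): the window must be more likely under the domain
  profile than under background. Rejections for this reason are labelled
  `low_score`.

Redundancy removal defaults to exact sequence identity with
first-occurrence-wins ordering; an identity threshold below 1 switches to
a local-alignment coverage rule. Molecular weight sums average residue
masses plus one water; the isoelectric point solves the
Henderson--Hasselbalch net-charge equation by bisection over a packaged
Bjellqvist-style pK set (N-terminus 7.50, C-terminus 3.55, D 4.05, E
4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0).

# Subfamily classification

The maximum-likelihood tree of the original workflow is replaced by
Poisson-corrected distances (`d = -ln(1 - p)`, p capped at 0.999) with
partial deletion (columns below 95% coverage dropped, configurable) and
neighbor joining, with column-resampling bootstrap. This is a documented
simplification: a four-clade classification of well-separated subfamilies
does not need likelihood tree search, and the distance pipeline is fully
specifiable and fast enough to bootstrap a thousand times in seconds.
Negative NJ branch estimates are clamped to zero with a per-tree count
recorded. Taxa are put in canonical (sorted) order before agglomeration
so that tie-breaks, and hence bootstrap supports, do not depend on input
order.

Subfamily labels are read off the tree by the anchored-clade rule: a
gene's label is the subfamily of the anchors in the smallest split side
containing the gene and at least one anchor; mixed-anchor sides yield an
explicit `"ambiguous"` label. This operationalizes what is usually done
by eye on a published tree. Independently, domain architecture gives a
second label through the rule table (HD+LZ only = I; +CPSCE = II;
+START+MEKHLA = III; +START without MEKHLA = IV), and disagreement is
logged per gene, never silently overwritten. Anchors default to the
synthetic archetype exemplars; user-supplied reference proteins can be
used instead.

# Motif discovery

`discover_motifs()` is a ZOOPS (zero-or-one occurrence per sequence)
expectation-maximization search: motifs are found one at a time, each
motif's sites are masked, and the search stops at `max_motifs` (default
15) or when information content per column falls below `ic_floor`
(default 0.5 bits). Widths are searched over a coarse grid within the
11--50 range (full range configurable). Numerical choices worth knowing:

* The EM objective is the observed-data log likelihood **plus** the
  Dirichlet smoothing term matching the M-step pseudocounts (MAP-EM);
  this penalized objective is what is guaranteed non-decreasing, and it
  is what `ll_trace` records.
* EM on planted motifs has a classic phase-shift failure mode. Each
  width runs many seeded starts, ranks them by a 3-iteration objective,
  iterates the best to convergence, and then applies phase-shift
  refinement: the PWM is rebuilt from the hard sites shifted by up to
  five columns and EM is rerun, keeping improvements.
* Site calls are hard: the argmax window of each sequence whose total
  site posterior exceeds 0.5 -- one occurrence per protein at most,
  which is what the ZOOPS model encodes.

# Duplication calling

Tandem pairs are same-chromosome genes whose nearest boundaries lie
within 50 kb (distance measured boundary-to-boundary; the window is
configurable). Records mapped to identical coordinates are alternative
transcripts of one locus and are collapsed before any pairing;
scaffold-bound genes are excluded from chromosome-based analyses and
reported.

Segmental candidates are scored by a seed-and-extend aligner
(`seeded_local_align()`): exact 12-mers seed ungapped X-drop extensions
(X-drop 20, match +1/mismatch -2); same-diagonal blocks are merged. Gaps
between homologous segments surface as several collinear blocks, which
`chain_blocks()` assembles by dynamic programming after discarding blocks
failing the strict per-block filters (length > 200 bp, identity > 85%);
ties break toward higher minimum identity, then earlier block order. A
pair is called segmental when the chained aligned length over the
concatenated 100-kb window (gene body excluded, either flank may
contribute) reaches `min_chain_span`, default 2,000 bp -- well above what
unrelated 100-kb windows produce (their chance seed matches never pass
the block filters) and far below planted duplication spans. The
`smith_waterman()` engine provides the exact affine-gap optimum for
short sequences and serves as an upper bound and cross-check on the
heuristic blocks.

# Promoter cis-elements

Promoters are the 1500 bp upstream of the translation start (minus-strand
genes: reverse complement downstream of the gene end), truncated with a
flag at contig edges. Equating the transcription start with ATG is the
workflow's operational choice, recorded here: 5' UTRs are not modelled.
Scanning expands IUPAC codes to character classes; `N` in the scanned
sequence never matches; overlapping occurrences are all reported; reverse
strand hits are reported at forward coordinates and palindromic
double-counts can be collapsed. The packaged catalog of common plant
elements (ABRE, MBS, HSE, LTR, G-box, ...) is an editable TSV fixture of
this package -- patterns are not asserted facts about any database.

Overrepresentation is per promoter presence/absence: for element $e$ and
subfamily $s$ with $n_s$ members of which $k$ contain $e$, and $p_0$ the
proportion of all family promoters containing $e$,
$p = P(X \ge k), X \sim \mathrm{Binomial}(n_s, p_0)$, computed exactly.
Benjamini--Hochberg adjustment is applied within each subfamily and both
raw and adjusted values are reported. Presence/absence (not occurrence
counts) is forced by the binomial model with n equal to subfamily size;
the family itself (not the genome) is the background, matching the
implied reference set of a within-family comparison.

# Expression and qPCR

A gene is expressed where FPKM strictly exceeds 1. Classes:
`constitutive` (all samples), `non_expressed` (none), `tissue_specific`
(the expressed set is exactly a configured tissue-group union), else
`partial`. Fold change is `log2((t + c)/(c0 + c))` with pseudocount
`c = 0.1` FPKM by default (configurable, including 0 to reproduce raw
ratios); "changed" means `|log2 fc| > 1`.

Relative qPCR expression is `2^-ddCt` with replicate Ct aggregated by
arithmetic mean; the calibrator sample is exactly 1 by construction, and
a constant shift of every Ct cancels. Duncan's multiple range test
assumes a balanced one-way design (unbalanced input is rejected, not
approximated): the pooled error mean square is the mean within-group
variance, and a range spanning $p$ sorted means is significant beyond
$R_p = q_p\sqrt{\mathrm{MSE}/n}$ where $q_p$ is the studentized-range
quantile at Duncan's protection level $1-(1-\alpha)^{p-1}$ (computed by
`qtukey`; it reproduces the classical printed tables to their two
decimals). Letters mark maximal non-significant stretches, so groups
sharing a letter are contiguous in mean order; exact ties always share,
which makes the zero-variance all-equal case a single letter while
zero-variance unequal means get all-distinct letters.

# The synthetic-data generator

`scenario_config()` fixes the study conditions; its defaults emulate the
design the pipeline targets:

* 57 true family members in subfamilies of 23/14/9/11, plus 68 decoys
  (30 homeodomain-only, 28 zipper-only, 10 exact duplicates) for a
  125-sequence candidate pool;
* 18 chromosomes with three scaffold-bound genes and two same-locus
  transcript pairs; at most eight genes on the first chromosome and a
  single gene on three others; same-chromosome spacing always exceeds
  50 kb, so the planted tandem truth is empty;
* five segmental pairs (two in subfamily II, one in each other
  subfamily), each planting a point-mutated copy of the partner's 100-kb
  flanking window at 92% identity -- comfortably above the 85% block
  filter while exercising it;
* exon counts of 1--3 (I), 3--4 (II), 18 (III) and 9--10 (IV) per gene;
* each subfamily's focal promoter element (ABRE, HSE, GARE-motif, MBS)
  planted in 90% of its promoters against a 15% background for all
  catalog elements; a segmental partner's promoter is the copied one, and
  the truth table records the copied layout;
* five tissue samples with 25 constitutive, 8 silent, 12 root-specific
  and 12 partial genes (log-normal expressed values bounded above 1;
  silent values below 1); drought contrasts with exactly 18
  leaf-changed and 24 root-changed genes at 8-fold effect size;
* triplicate qPCR tables for 12 targets (three per subfamily) over four
  timepoints with true ratios (1, 4, 0.25, 2), Ct noise SD 0.15 cycles,
  and an exactly constant reference gene.

Domain content is generated hierarchically: hand-written consensus
exemplars for HD, LZ, CPSCE, START and MEKHLA (information-rich fixtures
of this package, not database models) are diverged once per subfamily
(15% per position) and then per member (5%; 0 gives the noiseless
scenarios used in tests). Background sequence is i.i.d. uniform -- the
simplest null for E-value calibration. The generator also emits the
domain-block concatenation as a ready-made alignment (gaps where a domain
is absent), which is what the tree stage consumes; a general-purpose
progressive aligner is intentionally out of scope.

What the generator does **not** emulate -- and hence what green tests do
not certify about real data: insertions and deletions inside domains
(the scanner is ungapped), compositional bias and repeats, alternative
splicing beyond identical-coordinate transcript pairs, genome-version
mismatches between annotation releases (the generator uses one coherent
namespace), library-size effects in FPKM, and qPCR amplification
efficiency deviating from 2.

# Problem sizes and determinism

All randomness flows through a single seed per scenario or call, and
identical configurations produce byte-identical files (the run manifest
omits the wall-clock timestamp for exactly this reason; it is written to
a sidecar file instead). The test suite runs the full 125-protein
identification, the full 57-gene + 4-anchor tree, and the full 18
chromosome / five-pair duplication reconstruction; property batteries use
500 random instances for the chaining and alignment oracles, all 4--6
taxon topologies for neighbor joining, and 300 randomized exact-binomial
checks. Bootstrap counts in the test pipeline runs are reduced (25--60
replicates) because the supports they assert are categorical; the
pipeline default remains 1000.

# Known limitations

* The ungapped scanner will under-score domains that contain insertions
  relative to the profile; real proteomes should tolerate a weaker
  E-value threshold or longer profiles.
* Empirical E-values cannot go below the shuffle-count floor; claiming
  database-scale significance requires raising `null_shuffles`.
* The anchored-clade rule requires at least one anchor per subfamily in
  the tree; with sparse or misplaced anchors, genes come back
  `"ambiguous"` rather than silently mislabelled.
* Duncan's test is implemented for balanced designs only, matching the
  triplicate layout it is used for here.
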