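---
title: "DeepSAGE tag-count analysis: models, parameters and design choices"
author: "deepsage package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DeepSAGE tag-count analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepsage)
```

# The measurement model

DeepSAGE represents each transcript molecule by a fixed 21-nt tag: the
*Nla*III recognition site `CATG` plus the 17 nt that *Mme*I releases
downstream of it. Because the cDNA is held on Oligo(dT) beads, only the
3′-terminal *Nla*III fragment survives washing, so the sequenced tag comes
from the 3′-most usable `CATG` site of the transcript. A library is then a
multiset of 21-mers, and gene expression is the count of unambiguously
mapped tag copies, normalized to tags per million clean tags
(TPM = count / clean total × 10⁶ — a pure depth normalization, not the
modern length-normalized RNA-seq TPM; tags are fixed-length so no length
correction applies).

This vignette records the statistical model, every tunable that matters,
what the simulator does and does not emulate, and the places where the
design was genuinely open.

# The simulator

`simulate_transcriptome()` draws random transcripts (default 200–2000 nt)
and forces a configurable fraction (default 0.9) to carry a `CATG` with a
full 17-nt runway; the remainder are scrubbed of usable sites and model
the unmappable fraction of any real transcriptome.
`assign_ground_truth()` draws baseline relative abundances from a
log-normal (meanlog 0, sdlog 1.5 — heavy-tailed enough that the 2–5-copy
class dominates distinct tags while a handful of genes carry a large share
of copies, the shape seen in real tag libraries) and flags exactly
`round(de_fraction × n_genes)` genes per treatment condition with a fold
change from `fold_values`, up with probability `prob_up` (default 0.5)
and otherwise the reciprocal. Condition abundances are baseline × fold,
renormalized to sum to one — proportions are the only scale a counting
assay can see (more on the consequences below).

`simulate_tag_reads()` emits exactly `depth` reads of exactly 49 nt: the
canonical (3′-most) tag followed by the 3′ adapter (default a 28-nt
Illumina-style sequence, so 21 + 28 = 49), with

* `empty_read_rate` (default 0.05) of reads being pure adapter — these
  model adapter self-ligation and are what the clean-up stage counts as
  "empty reads";
* independent per-base substitution errors at `error_rate` (default
  0.005, a typical short-read figure). Errors are substitutions only:
  tags are fixed-length, and an indel would simply shift the adapter out
  of position 22 and be removed by the length guard, so simulating indels
  would only re-test that filter.

Everything is deterministic given `seed`; the generator restores the
caller's RNG state.

What the simulator does **not** emulate: PCR amplification bias, GC
effects, quality-score realism, positional error profiles, incomplete
*Nla*III digestion (tags from non-3′-most sites) and antisense
transcription. Passing recovery tests therefore demonstrate correctness
of the pipeline's logic under idealized chemistry, not robustness to
every artefact of real libraries; mapping nonetheless indexes *all* CATG
sites on both strands so that real-data deviations from the canonical-tag
assumption degrade gracefully rather than silently.

# Clean-tag filtering

`extract_clean_tags()` applies, in order: (1) empty-read removal (read
begins with the adapter); (2) low-quality removal — "low quality" is not
defined in the classical protocol text, so it is operationalized
minimally as *no `CATG` prefix or an `N` inside the 21-nt tag region*;
(3) the too-long/too-short guard — the adapter must follow at position
22; (4) the copy-number filter, dropping tags seen fewer than `min_copy`
(default 2) times *within one library, before any cross-library
comparison*. Copies removed at each stage are logged so that
`raw_total = clean_total + sum(filter_log)` always holds; the per-stage
ledger is what a report table's "percent of raw" arithmetic runs on.
Report percentages round half-away-from-zero to two decimals — the
convention that reproduces published report tables exactly (base R's
`round()` is half-to-even and does not).

# Virtual-tag mapping

`build_index()` enumerates every `CATG` occurrence with ≥ 17 nt
downstream on the transcript and on its reverse complement. All sites are
indexed, not only the 3′-most: against cross-species reference
transcriptomes the 3′ annotation is unreliable, so mapping must tolerate
any site even though the chemistry emits 3′-most tags.

`map_tags()` resolves each distinct clean tag:

* exact hits take precedence — a tag with an exact hit never acquires
  1-mismatch targets;
* at its best mismatch level, one gene → **unambiguous** (multi-position
  hits within a single gene stay unambiguous; a gene hit on both strands
  resolves sense-first, a deterministic and conservative tie-break),
  two or more genes → **ambiguous** (excluded from all gene counts),
  no hit → **unknown**;
* the single allowed mismatch is confined to the 17-nt suffix by default
  (`anchor_exact = TRUE`): the anchor is the enzymatic recognition site
  and was verified upstream. Since clean tags and virtual tags both carry
  the `CATG` prefix, an anchor-position mismatch could only ever pair a
  tag with a non-`CATG` 21-mer, which the index cannot contain — the
  switch is therefore inert for well-formed inputs and exists for
  explicitness; the test suite asserts both policies agree.

Copy conservation holds by construction: sense-unambiguous +
antisense-unambiguous + ambiguous + unknown copies = the library's clean
total. Internally coordinates are 0-based; reports are 1-based via the
printed `pos` offsets.

# The Audic–Claverie test and the call rule

Conditional on observing `x` copies in a library of `N1` clean tags, the
count in a second library of `N2` follows

$$p(y \mid x) = \left(\tfrac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

a negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$. The two-sided p-value is
$\min\!\big(1,\; 2\min(\sum_{k \le y} p(k|x),\; \sum_{k \ge y} p(k|x))\big)$.

Numerical choices: terms are evaluated in log space with `lgamma`; the
lower tail is a direct sum (at most $y+1$ terms); the upper tail uses the
complement $1 - \sum_{k<y}$ only while that is well-conditioned
(complement ≥ 0.1) and otherwise is summed directly in chunks with a
geometric remainder bound, so the *minor* tail — the one that decides the
p-value — always keeps full relative precision. Against an
exact-rational-arithmetic oracle the implementation agrees to better than
$10^{-11}$ relative error across $x, y \le 100$ and
$N \in \{10^4, 10^6, 10^7\}$, including p-values near $10^{-300}$. A
total-underflow guard floors p at the smallest normal double so p stays
in (0, 1].

One property worth stating because it is easy to assume otherwise: the
test is **not** orientation-symmetric. Conditioning on the first count
means $p(x,y,N_1,N_2) \ne p(y,x,N_2,N_1)$ in general — with equal library
sizes, $p(10,0) = 2^{-10}$ but $p(0,10) = 2^{-9}$, and the two
orientations always agree within a factor of 2 at equal depths (each tail
shifts by exactly one binomial trial). The package follows the cited
convention of conditioning on the first (control) library.

DEG calling (`call_degs`) tests every gene with a nonzero count in either
library (zero–zero genes carry no information and would only dilute the
FDR denominator), adjusts with Benjamini–Hochberg (`BY` available; the
FDR citation in the source protocol names no procedure, and BH is the
field default), and requires both FDR ≤ `alpha` (default 0.01) and
|log₂ ratio| ≥ `min_abs_log2` (default 1, i.e. two-fold). The ratio is
computed on TPM with a detection floor of 0.01 TPM substituted for
undetected genes — the floor value is pinned by published tables in which
a gene absent in one library and at 1.42 TPM in the other reports
log₂ 7.1 = log₂(1.42/0.01) at one decimal. Published per-gene TPM pairs
reproduce their printed log₂ values at printed precision under exactly
this rule, which is why the floor is applied to TPM rather than to raw
counts.

# QC

`saturation_curve()` permutes the library once at the copy level
(sampling without replacement — "sequencing amount" means total tag
copies, not distinct tags) and reports distinct unambiguously-mapped
genes at each depth; nesting the grid in one permutation makes the curve
non-decreasing by construction and fixed given the seed.
`library_correlation()` computes Pearson r on per-gene TPM (not raw
counts, since libraries differ in depth; a log2(TPM+1) option exists);
technical replicates of one ground truth at 10⁵ reads correlate above
0.95 in the test suite. `tag_class_report()` bins tags into the six
classical copy-number classes with inclusive boundaries (100 → "51–100",
101 → ">100").

# qRT-PCR quantification

`ddct_fold_change()` implements pure 2^−ΔΔCт: technical replicates are
averaged (arithmetic mean of Ct, configurable to median) before
differencing, ΔCt = Ct(target) − Ct(reference) per condition,
ΔΔCt = ΔCt(treated) − ΔCt(calibrator). No amplification-efficiency
correction is applied — that is a deliberately excluded variant, not an
omission. Exactly one endogenous-control gene is required per sample;
fold changes are reciprocal under swapping treated/calibrator, and adding
a constant to every Ct of a sample cancels through the reference.

# Benchmark studies and their problem sizes

Two study harnesses ship with the package because they define what
"working" means here. `null_rejection_rate()` simulates pairs of
libraries from identical ground truth (10 pairs, 500 genes, 10⁵ reads
each) and counts DEG calls: every call is a type-I error, and the pooled
rate stays within `alpha` plus three binomial standard deviations (in
practice it is zero — the joint FDR + fold-change rule is conservative
under the null). `deg_recovery()` plants 10 % of genes at fold 8
(10 pairs, 500 genes, 2×10⁵ reads, error rate 0.005) and reports
sensitivity on DE genes with baseline ≥ 50 TPM (about 0.87) and the
empirical false-discovery proportion. These sizes keep each study under
a minute while leaving Monte-Carlo error well below the margins being
tested.

## A compositional caveat, documented deliberately

The recovery study's false-discovery proportion, measured against the
*assigned* DE labels, is far above the nominal FDR (≈ 0.4 pooled) — and
this is a property of proportion-based DGE, not of the implementation.
Sampling probabilities must sum to one, so assigning fold 8 to 10 % of a
heavy-tailed abundance vector rescales every other gene by
$r = \sum b_g f_g / \sum b_g$; when a top-share gene happens to be drawn
up-regulated, $r$ reaches 2, every non-DE gene's relative abundance truly
halves, and the Audic–Claverie test — which tests equality of
*proportions* — correctly rejects for well-expressed non-DE genes.
Calling those rejections "false" conflates the test's error rate with the
identifiability limit of relative-abundance data. The type-I study above,
where composition is untouched, shows the test itself is calibrated.
The generator keeps the neutral coin-flip direction default rather than a
mass-balanced design precisely so this limitation stays visible; analyses
that need absolute-expression conclusions from tag counts require
spike-ins or composition-robust normalization, both outside this
package's scope.

# Degenerate inputs and edge behaviour

All-filtered read sets yield a valid empty library with a warning, not an
error. Genes without a usable `CATG` site emit no reads and are simply
absent from the index (reported via `n_genes_with_catg`). An adapter
shorter than 28 nt cannot fill a 49-nt read and is a parameter error.
Zero clean totals make TPM undefined and error out. Correlation of
zero-variance TPM vectors is an explicit error rather than NA. Ties in
mapping are broken deterministically (gene-sorted, sense-first) so that
identical inputs give byte-identical outputs everywhere, which
`run_pipeline()` inherits: re-running a config reproduces every TSV
byte-for-byte.

# Known limitations

* Mapping is transcriptome-, not genome-based; BLAST-style annotation and
  cross-species orthology are out of scope.
* The dispersion model is the Audic–Claverie conditional binomial — no
  biological-replicate overdispersion (negative-binomial GLMs in the
  DESeq2/edgeR sense) because the design has one library per condition.
* Enrichment is a flat hypergeometric test per term; no ontology DAG
  propagation.
* Published dataset-bound quantities (total DEG counts, class
  percentages of the real libraries) depend on raw data that was never
  deposited; the package reproduces the report *arithmetic* exactly and
  covers the dataset-bound claims qualitatively through simulation.
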