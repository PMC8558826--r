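---
title: "Methods: cross-tissue ligand–receptor co-expression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue ligand–receptor co-expression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lratlas)
```

## The screening model

The screen is directional: a **receiver** tissue contributes receptor
expression, a **sender** tissue contributes ligand expression, and a
ligand–receptor database supplies the edges between them. It makes three
deliberate simplifications:

* **Transcript abundance stands in for signaling capacity.** Mean TPM per
  gene is the only evidence used; protein abundance, secretion and
  localization are outside the model. This is the standard caveat of every
  expression-based crosstalk screen.
* **Thresholds, not statistics.** A pair is interesting when both sides
  clear fixed TPM cutoffs. No significance is attached to co-expression —
  with 4–5 replicates per tissue a threshold classification is more honest
  than a correlation p-value, and it makes every count in the report
  exactly reproducible.
* **The database is an input, not an inference.** Which genes count as
  receptors, which ligands they bind, and which enzyme gene proxies a
  non-protein ligand are user-supplied curation. The shipped
  `default_pair_db()` is a small literature-derived fixture for
  demonstration and testing; real screens should supply a full atlas.

### Quantification

`compute_tpm()` implements the standard transcripts-per-million
definition: per sample, counts are divided by transcript length in kb and
rescaled to sum to $10^6$,
$$\mathrm{TPM}_i = 10^6\,\frac{c_i/\ell_i}{\sum_j c_j/\ell_j}.$$
Column sums of $10^6$ (relative tolerance $10^{-9}$) and invariance to
per-sample count scaling are enforced by tests. TPM supplied directly is
never renormalized: upstream quantifiers legitimately produce columns that
do not sum to exactly $10^6$ (multi-mapping, filtering), and renormalizing
would silently change the user's values. Replicate averaging is the
unweighted arithmetic mean, the convention in the source datasets this
design emulates.

### Cutoffs and tiers

All cutoffs live in `screen_config()` (units: TPM):

| parameter | default | role |
|---|---|---|
| `expressed_cutoff` | 2 | gene counts as expressed; gate for receptors and autocrine ligands |
| `high_cutoff` | 10 | "highly expressed"; defines the quadrants (log10 TPM > 1) |
| `very_high_cutoff` | 100 | "very highly expressed" tier in receptor records |
| `ligand_plot_cutoff` | 1 | sender-side floor for drawing a pair in scatter figures |
| `top_n` | 50 | depth of the ranked bar charts |

Every comparison is a **strict** inequality: the conventions these cutoffs
come from are written as ">2", ">10", ">100", ">1", so a mean of exactly
2 TPM is *not* expressed and exactly 10 is *not* high. The config
validator enforces `0 < ligand_plot_cutoff ≤ expressed_cutoff <
high_cutoff < very_high_cutoff`, so the tiers always nest.

### Quadrants, plotting rule and proxy pairs

Each (receptor, ligand, category) edge is classified `high_high`,
`high_low`, `low_high` or `low_low` by strict comparison of both mean TPMs
against `high_cutoff`. Two counting conventions coexist and both are
stored:

* **Headline quadrant counts** include *all* pairs of a category,
  irrespective of the plot-inclusion rule — the rule governs what the
  scatter panels display, not what is counted.
* **Plotted-only counts** are stored alongside for figure parity.

Pairs whose ligand is a synthesis-enzyme proxy get quadrants computed on
the proxy gene's expression but are excluded from the headline
protein-ligand high/high counts (`n_protein`): an enzyme transcript is
only indirect evidence of the small molecule, so those pairs are reported
in their own panel. A pair carrying several categories is counted once per
category panel. A ligand gene absent from the sender table is assigned TPM
0 with an explicit `ligand_missing` flag and a logged message — never
silently dropped — because absence from a table (not quantified) and
absence of expression (TPM 0) are different facts the user should see.

### Orphans, curation and the autocrine inventory

The receptor universe is `unique(db$receptor)` plus curation
force-includes minus excludes; expression filtering happens after, so an
included gene below 2 TPM still drops out. Orphans are exactly the
expressed receptors with an empty ligand set. Two conventions were left
open by the source material and resolved here: the orphans are counted
*within* the expressed receptor total (they are receptors like any other),
and the autocrine ligand inventory uses the same 2-TPM expressed cutoff as
the receptors (no separate cutoff was ever stated; using one config keeps
the report internally consistent). The inventory includes only
protein-ligand genes — proxies encode enzymes, not ligands.

Ranking ties (equal mean TPM) are broken by gene symbol ascending so that
top-N lists are deterministic; no tie rule is inherited from elsewhere, so
the package fixes its own.

### Overrepresentation

`overrepresentation()` is a generic hypergeometric upper-tail test
$P(X \ge k)$ with BH adjustment across the tested sets, replacing
proprietary pathway engines whose statistic and gene sets are not
reproducible. The universe defaults to all genes of the receiver table;
pathway membership comes from user GMT files. Raw `p < alpha` drives the
`significant` flag (matching the convention of commercial ORA tools);
q-values are reported alongside and are the better quantity to threshold.

## The synthetic generator

`simulate_crosstalk()` emulates the study conditions the screen was built
for: 4 receiver replicates and 5 sender replicates, 10–20k gene symbols,
heavy-tailed background expression (log10 TPM ~ Normal(−0.5, 1), so the
median gene sits at 0.3 TPM and most genes are below the expressed
cutoff), a pair database with multi-ligand receptors, shared-ligand
receptor components, enzyme-proxy pairs, orphan receptors, and a planted
set of high/high pairs.

Numerical design of the planting guarantee, with high cutoff $h$ and
margin $m > 1$:

* planted receptors and ligands draw true means log-uniformly from
  $[mh, 10\,mh]$;
* every gene that could create a false high/high pair — non-planted
  receptors, and the non-planted ligands of planted receptors — is
  resampled below $h/m$;
* replicates are `true mean × 10^rnorm(0, noise_sigma)`; with the default
  `noise_sigma = 0.1` the replicate-averaged log10 error is ≈ 0.05, an
  order of magnitude smaller than the log10 margin of 0.3, so recovery of
  the planted set with zero false positives and negatives is expected and
  is verified empirically over 100 seeds.

TPM is simulated directly on the TPM scale without renormalization, so the
planted margins are exact; `simulate_counts_from_tpm()` is a secondary
Poisson counts-mode generator for exercising `compute_tpm()`. Orphans are
omitted from the pair list and delivered through the returned curation
include list, pinned into the expressed-but-not-high band so the orphan
count is deterministic. The generator stores per-gene true means and an
`expected` block computed by running the screen's own rules on the
noise-free means — the truth-consistency invariant.

What the generator does **not** emulate: bovine transcriptome structure,
gene-length or GC effects, count-level sampling noise in the main path,
correlated replicates, or between-condition differential expression.
Passing tests therefore demonstrate the correctness of the screening
logic under its stated assumptions, not the biological validity of any
particular real-data screen.

## Problem sizes and determinism

The test suite runs the oracle-equivalence property on 1000 random small
instances against independent brute-force reimplementations, the planted
recovery check on 100 seeds at 2000 genes / 150 receptors / 20 planted
pairs, and exhaustive hypergeometric enumeration for universes up to 12
genes; these sizes keep the default suite at a few minutes on one CPU
while the properties themselves are size-free. Given identical inputs and
config, the screen is fully deterministic (byte-identical report
serialization), and the generator is fully determined by its seed.

## Degenerate inputs

Empty expression matrices, all-zero samples, non-positive lengths,
negative TPM, duplicate symbols (default policy: error; `sum` for counts,
`max` for TPM, both logged), malformed database rows (unknown category,
proxy without molecule, duplicate edge) and overlapping curation lists all
raise typed errors naming the offending sample, row or line. Zero or
missing ligand TPM cannot be log-plotted; such pairs are excluded by the
plot rule anyway (ligand TPM must exceed 1), so no pseudo-count is
introduced anywhere.

## Known limitations

* Symbol-based matching only (uppercased); no ortholog mapping. Cross-
  species screens inherit whatever symbol harmonization the user applied.
* Replicate counts are whatever the input tables contain; the pipeline
  logs them but cannot adjudicate upstream inconsistencies in how many
  samples an average was taken over.
* No statistical model of co-expression, no directionality beyond
  sender→receiver, no extracellular-vesicle signaling.
* The shipped pair database is a demonstration fixture; its proxy-enzyme
  assignments follow the source literature verbatim (including the
  acetylcholine entry recorded under ACHE) and are documented, not
  endorsed.
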