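---
title: "Rank-based 1D and 2D annotation enrichment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based 1D and 2D annotation enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrich2d)
```

## The problem

A quantitative proteomics experiment assigns one number — a log ratio, a log
abundance, a test statistic — to each of thousands of protein groups. The
recurring question is not about single proteins but about annotation terms:
does a complex, pathway, domain family or localization class sit
systematically higher or lower in that distribution than the rest of the
measured proteome? And when a second omics dimension is available (mRNA
ratios, copy-number ratios), does a term deviate from the *joint*
distribution of the two dimensions — concordantly, in only one dimension, or
in opposite directions?

`enrich2d` answers both questions with rank-based tests that make no
distributional assumption, always compare a term against the measured
population itself (never against the whole genome, which would import
detectability bias), and need no up/down-regulation cutoff.

## The 1D test

All values in the chosen column are replaced by their ranks (mid-ranks for
ties). For a term with $n_1$ members among the $n$ retained rows, the
two-sample Wilcoxon–Mann–Whitney statistic is

$$U = R_1 - \frac{n_1 (n_1 + 1)}{2},$$

with $R_1$ the rank sum of the members. The test is two-sided by default
(terms may concentrate at either end); one-sided variants are exposed.
Significant terms receive the position score

$$s = \frac{2 (\bar R_1 - \bar R_2)}{n} \in [-1, 1],$$

the scaled difference between the mean rank of the members ($\bar R_1$) and
of the complement ($\bar R_2$). $s = 1$ exactly when the members occupy the
top $n_1$ ranks, $-1$ at the bottom ranks; a small $|s|$ with a significant
p-value indicates a slight but consistent collective shift of a large term.

**p-value computation.** For $n_1 n_2 \le 400$ the p-value comes from the
exact conditional null distribution of the rank sum, computed by dynamic
programming over the (doubled, hence integer) mid-ranks — equivalent to
enumerating all $\binom{n}{n_1}$ group assignments, ties included. Above
that, the standard normal approximation with tie correction and continuity
correction is used; at genome scale ($n$ in the thousands) the two are
indistinguishable. The test suite checks the exact branch against literal
enumeration for every configuration with $n \le 12$ and both branches
against `stats::wilcox.test`.

## The 2D test

Ranks are computed in each dimension separately (a natural ordering of 2D
points does not exist, but the WMW test is equivalent to a pooled t-test on
ranks, and the t-test generalises to MANOVA). For two groups in two
dimensions the MANOVA statistic is proportional to the quadratic form

$$Q = \frac{s_{xx} d_y^2 + s_{yy} d_x^2 - 2 s_{xy} d_x d_y}
          {s_{xx} s_{yy} - s_{xy}^2},$$

where $d_x = \bar x_1 - \bar x_2$, $d_y = \bar y_1 - \bar y_2$ are the
differences of group mean ranks and $s_{xx}, s_{yy}, s_{xy}$ are the pooled
within-group sums of squares and cross-products of the ranks.

**Choice of the proportionality constant.** The quadratic form determines
the test only up to scale. With exactly two groups, MANOVA reduces to
Hotelling's two-sample $T^2 = \frac{n_1 n_2}{n} (n - 2)\, Q$, and
$F = \frac{n-3}{2(n-2)} T^2$ follows an exact $F(2, n-3)$ null under
normality. We adopt this mapping as the reference distribution. On ranks it
is an approximation, so it is validated empirically rather than assumed: the
tests compare the resulting p-values against a 50,000-draw permutation
oracle (agreement within 0.03 on random instances) and verify global-null
calibration at $\alpha \in \{0.01, 0.05\}$ with 10,000 random terms on 5,000
rows. No additional tie correction is applied to the F reference; ties enter
through the mid-ranks, and the permutation checks guard calibration under
heavy ties.

The 2D score is the pair $(s_x, s_y)$, each coordinate the 1D score,
confined to $[-1,1]^2$. Concordant terms sit near the diagonal,
single-dimension terms near an axis, anti-correlated terms in the
off-diagonal quadrants. No thresholding on $|s|$ is applied: the empty
region around the origin seen in real score plots is a consequence of the
significance filter, not a rule.

**Degenerate scatter.** If $s_{xx} s_{yy} - s_{xy}^2 \le
10^{-12}\, s_{xx} s_{yy}$ (e.g. the two rank vectors are collinear within
groups), the term is reported with status `singular` rather than given an
artificial $p = 0$.

## Multiple testing and truncation

Annotation categories bring thousands of terms, so p-values are adjusted by
the Benjamini–Hochberg step-up procedure. The default adjusts across all
requested categories pooled in one run; a per-category option exists. GO's
term relatedness makes pooled correction conservative (the number of
effectively independent tests is smaller than the count used), so there is
no danger of over-reporting. Hit lists are truncated either at a raw
p-value or at an FDR threshold; the threshold is a fraction in $(0,1)$,
never a percentage. The default reporting FDR is 0.02 for 1D runs; 2D score
maps are often more informative at laxer thresholds such as 0.15 — both are
user parameters.

**Minimum term size.** Terms need at least 2 members present among the
retained rows by default (configurable down to 1 for 1D; the 2D test
requires 2 per group for within-group scatter). Terms with no member in the
table are dropped outright; terms whose members all carry missing values are
reported as `skipped_small`. Rows with missing values are removed *before*
ranking, so the complement group is always the retained measured proteome.

## Building the matched table

Upstream of the tests the package implements the bookkeeping that makes a
protein-versus-transcript table well defined:

* **Protein grouping** (`group_proteins()`): proteins with identical
  identified-peptide sets are merged; a protein whose set is contained in
  another's joins that protein's group; members are ordered by descending
  peptide count. Remaining shared peptides are razor-assigned to the group
  with the most identifications. The razor tie-break (lexicographically
  smallest group id) and the choice of the *largest* superset when several
  contain a set are not forced by the grouping principle; they were fixed
  once for reproducibility.
* **Group annotation** (`select_group_terms()`): the group carries the
  pooled annotation of every member with at least half the leading
  protein's peptide count — "at least half" read as a real-valued
  comparison, so a 5-peptide member passes against a 10-peptide leader.
  Members below the threshold are never consulted, even if the group would
  otherwise be term-less. UniProt isoform suffixes are stripped for lookup
  (configurable off).
* **Probe matching** (`match_probesets()`): protein-centric — zero matching
  probes exclude the group from 2D analysis, one is used directly, several
  are collapsed by the point-wise median. A probe annotated to proteins of
  several groups contributes to each of them.
* **CGH collapse** (`collapse_cgh()`): each copy-number probe goes to the
  gene containing it, otherwise to the nearest interval midpoint (distance
  ties to the lower-coordinate gene; intervals are 0-based half-open — all
  three conventions chosen once, for determinism); per-gene values are
  combined by the median.
* **Log transform** (`log_transform()`): ratios and abundances are analysed
  on log scale. The mean of a two-fold up- and a two-fold down-regulation
  is $(2 + 1/2)/2 = 1.25 \ne 1$ on the raw scale but
  $(\log 2 + \log \tfrac12)/2 = 0$ on the log scale; the same applies to
  medians, whose computation averages two central values at even counts.
  Base 2 is the default for ratios.

## The synthetic-data generator

`simulate_table()` emulates the features the tests rely on: a unimodal
background (standard normal for log-ratios; for log10 abundance-like data a
normal around 7), optional x–y correlation $\rho$, random-membership null
terms with sizes uniform on 10–100 (the bulk of GO/KEGG term sizes in a
deep proteome), independently missing cells, and planted terms shifted by
$(\delta_x, \delta_y)$ in background-SD units. Defaults — 5,000 rows,
planted size 50, $\delta = 1.5$ SD — correspond to a deep single-run
proteome with a clearly regulated mid-size complex.

What the generator does **not** emulate: intensity-dependent missingness
(real missing values concentrate at low abundance), correlated noise between
members of the same complex, tie structure from identical quantification,
and the GO hierarchy's nested term overlap. Passing calibration and power
tests on this generator therefore shows the statistics are correct under
exchangeable backgrounds, not that real-data FDRs are exactly nominal —
dependence among related terms makes pooled BH conservative rather than
anti-conservative, which is the safe direction.

Simulation sizes used by the test suite and the acceptance script — 10,000
null terms on 5,000 rows for calibration, 100 replicates for power, 200
replicates (1,000 rows, 100 terms, 10% shifted) for realized FDR — were
chosen to make the binomial confidence bands tight relative to the effects
checked.

## Command-line interface

The installed script (`system.file("exec", "enrich2d", package =
"enrich2d")`) exposes `enrich1d`, `enrich2d`, `match` and `simulate`
subcommands. Quantitative columns are supplied as two equal-length lists
paired first-with-first, second-with-second; a length mismatch is rejected
before any computation. The CLI is a thin shell: every emitted number comes
from `enrich_1d()`/`enrich_2d()`, and the equivalence is itself under test.
Flag parsing is a small purpose-built loop because the interface needs
repeatable flags, subcommands and a key–value config file in combination.

## Known limitations

* The 2D F reference is asymptotic on ranks; for very small tables
  (tens of rows) permutation p-values are preferable — the package exposes
  the statistic so users can permute.
* Only two dimensions are supported; the MANOVA route generalises to more,
  but score interpretation and plotting do not carry over directly.
* GO term relatedness is not modelled; adjusted q-values are conservative
  under the pooled default.
* `parse_gmt()` and friends accept GMT, two-column TSV and categorical
  columns; OBO parsing and DAG ancestor propagation are out of scope.

## A worked example

```{r example}
sim <- simulate_table(sim_spec(
  n_rows = 2000, n_terms = 30,
  planted = data.frame(term_id = c("complex_up", "protein_only"),
                       size = 40, dx = 1.5, dy = c(1.5, 0)),
  seed = 7))
rec <- enrich_2d(sim$table, "x", "y", sim$terms)
head(rec[, c("term", "size", "p", "q", "sx", "sy")])
```

The two planted terms dominate the list with score pairs in the expected
regions; the null terms' q-values are spread uniformly.

```{r plot, fig.width = 6, fig.height = 5}
plot_scores_2d(truncate_records(rec, "fdr", 0.02))
```
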