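---
title: "Mining drug-drug interaction terms with a resampling null"
author: "ddimine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining drug-drug interaction terms with a resampling null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddimine)
```

## The model

For one query drug, the MEDLINE records retrieved for it are partitioned
into Group A — articles indexed with the MeSH descriptor "Drug
Interactions" — and Group B, the remainder. Every substance listed in
Group A other than the query drug is a candidate term; its observed
statistic is $f_t$, the number of distinct Group A records listing it.

The null hypothesis is that term $t$ is no more associated with the
interaction literature than with the drug's literature at large. Rather
than modelling that null analytically, it is built empirically: each of $S$
sampling iterations draws $n$ records uniformly **with replacement** from
Group B and records how many contain $t$. If $t$ is present in a fraction
$q$ of Group B, those counts are exactly $\mathrm{Binomial}(n, q)$, so the
empirical mean $\mu_t$ and sample standard deviation $\sigma_t$ converge on
$nq$ and $\sqrt{nq(1-q)}$ — the property the test suite asserts at
$S = 1000$ within four standard errors. The test statistic is
$Z_t = (f_t - \mu_t)/\sigma_t$ with a one-sided upper-tail normal p-value
$p_t = 1 - \Phi(Z_t)$; enrichment in the interaction literature is the only
alternative of interest. Benjamini–Hochberg adjustment is applied across
the tested terms, and a term is reported when $f_t \ge$ cutoff and adjusted
$p < \alpha$.

The assumptions this rests on are worth stating plainly. The normal
approximation to the binomial is what converts $Z_t$ into a p-value; it is
poor in the extreme tails and for very small $nq$, so reported p-values of
exactly zero mean "beyond resolution", not a literal impossibility. Terms
are tested marginally — correlations between substances (co-prescribed
drugs, enzyme families) are ignored by the test and only resurface in the
co-occurrence network.

## Parameters

* `sample_times` ($S$, default 1000) — sampling iterations per run. The
  standard error of $\mu_t$ shrinks as $1/\sqrt{S}$; 1000 makes the
  Monte-Carlo noise on $Z_t$ negligible next to the effect sizes of
  interest while keeping a full run around a second at desk scale.
* `cutoff` (default 4, i.e. frequency > 3) — minimum Group A frequency for
  a term to be tested and reported. Low-frequency terms are noise-prone
  (one stray indexing decision can produce them), and excluding them before
  adjustment keeps the multiple-testing family $m$ independent of that
  noise. Applying Benjamini–Hochberg *after* the cutoff was a genuinely
  open choice; we fix it because the alternative makes every reported
  p-value depend on how many unreportable rare terms the corpus happens to
  contain.
* `alpha` (default 0.05) — strict threshold on the adjusted p-value.
* `z_threshold` (default 1.645) — the one-sided normal critical value that
  corresponds to $\alpha = 0.05$. It is carried in the configuration and
  reported for reference; the significance decision itself uses only the
  adjusted p-value, since a separate Z filter would be redundant with it.
* `sample_size` ($n$, default |Group A|) — records drawn per iteration.
  Matching the Group A size puts $f_t$ and the null counts on the same
  scale, so no rescaling is needed before computing $Z_t$.
* `end_date` — inclusive publication-date cutoff (`YYYY/MM/DD`), modelling
  the end date of the literature search. Partial record dates complete to
  their earliest instant; records with uninterpretable dates are retained
  with a warning, because the filter emulates a search bound rather than a
  validity check.
* `seed` — the single RNG seed. Each iteration consumes exactly $n$ draws
  from one seeded stream, so a run is bit-reproducible and independent of
  any execution schedule.

## Numerical choices and degenerate inputs

* Sampling is **with replacement**. Independent uniform draws give the
  clean binomial null above and make iterations exchangeable; without
  replacement the null would be hypergeometric and depend on $n/|B|$.
* $\sigma_t$ uses the unbiased divisor $S - 1$. At $S = 1000$ this is
  numerically irrelevant, but a fixed convention is needed for exact
  reproducibility tests.
* $\sigma_t = 0$ (a term never, or always, drawn): the p-value is 0 when
  $f_t > \mu_t$ and 1 otherwise, with $Z_t$ reported as $\pm\infty$ (or 0
  when $f_t = \mu_t$). This is the limit of the one-sided test and avoids a
  division by zero; it is also why strong terms can carry an exact zero.
* Ties and ordering: result tables sort by frequency descending, then raw
  p ascending, then term; network edges sort lexicographically. Output
  files are therefore byte-identical across runs with the same seed.
* Degenerate corpora fail fast: an empty Group A (nothing to test) or an
  empty Group B (no null) is a fatal, per-drug error; in batch runs one
  drug's failure is recorded and the rest proceed.

## The group classifier

Which articles count as "interaction-related" is configurable. The default
classifies a record into Group A when its MeSH headings contain the
descriptor "Drug Interactions" (case-insensitive, ignoring subheading
qualifiers and the major-topic marker) — the only interaction signal
present inside the record structure itself. Any function from a records
tibble to a logical vector can be injected in its place, e.g. a keyword
search over titles.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` realises a two-group corpus in which each catalogue
term enters each record independently with a group-specific probability
($p_a$ in Group A, $p_b$ in Group B), every record lists the query drug,
and Group A records carry the "Drug Interactions" descriptor. That is
precisely the data-generating process under which the sampling null is
exact, which is what makes the generator a legitimate oracle: planted
enrichments ($p_a > p_b$) must be recovered, equal-prevalence terms must be
rejected at close to the nominal rate, and the truth table written beside
the corpus carries the realised prevalences tests compare against.

It deliberately does **not** mimic real literature: substance terms in real
records are correlated (drug classes, enzyme panels), prevalences are
heavy-tailed rather than chosen, indexing practice drifts over time, and
MeSH vocabulary is far richer. Passing the synthetic suite therefore
demonstrates that the statistic, its calibration and the plumbing are
correct — not that any particular real-corpus result is clinically valid.
Correlated-term generation is a natural extension hook.

The problem sizes used throughout the tests and the reproduction script —
Group A of 500, Group B of 2000, 1000 sampling iterations, up to 200
catalogue terms, 100 seeded replicates for the recovery rate — were chosen
as a realistic desk-scale working point: they match the order of magnitude
of per-drug literature corpora (per-drug interaction-article counts for
common drugs run from a few hundred to ~2000) while keeping any single run
around a second.

## Design choices on open points

* **Reported p-values are the adjusted ones**, and the published
  significance filter ("frequency > 3, adjusted p < 0.05") is implemented
  as `frequency >= 4 & p_adjusted < alpha` with both bounds exact.
* **The query drug is excluded** both as a candidate term and as a network
  node: every retrieved record contains it, so it carries no enrichment
  information and would connect to every node.
* **Network edges are computed over Group A only.** The network's purpose
  is to show which significant terms are discussed together in the
  interaction literature; background co-mentions answer a different
  question. Edges have no minimum-weight threshold by default
  (`min_weight` is exposed).
* **Retrieval is an injectable transport.** Live PubMed access
  (E-utilities esearch + efetch) is genuinely optional: all analysis
  operates on local MEDLINE text, and tests exercise the retrieval
  interface only through canned transports.

## Known limitations

* Substance indexing is the ceiling: substances cover chemicals and
  reaction-related enzymes, so actors absent from that field (notably
  transporters) cannot be found, and matching is exact on the controlled
  vocabulary strings.
* The normal tail approximation makes very small p-values qualitative;
  ranking is by frequency first for exactly that reason.
* A marginal test cannot distinguish a true interaction partner from a
  term that merely rides along with one (confounding by co-prescription);
  the gold-standard comparison bundled with the package shows roughly a
  fifth of significant drug terms are not confirmed interactions.
* MEDLINE support is intentionally narrow: PMID, title, journal, date,
  MeSH and substance fields; author/grant fields and the XML dialect are
  out of scope.
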