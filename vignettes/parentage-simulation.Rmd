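---
title: "Simulating false inclusion of relatives in STR parentage testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating false inclusion of relatives in STR parentage testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(parentsim)
```

## The question the package answers

In a paternity case the laboratory types an alleged father and a child (a
*duo*, when the mother is unavailable) or the alleged father, mother and
child (a *trio*) at a panel of autosomal STR loci, and either *excludes*
the man or reports a paternity index. When the man tested is not the
father but a close relative of the true father — the child's full sibling,
the paternal grandfather, a paternal uncle, a paternal half sibling, or a
first cousin — he shares an elevated fraction of alleles with the child
and may escape exclusion at every locus: a *false inclusion*. `parentsim`
quantifies that risk by Monte-Carlo simulation: it generates families over
three generations from population allele frequencies and tabulates, for
each relationship, how many of the simulated alleged-father/child pairs
show 0, 1, 2, ... mismatching loci, together with likelihood-ratio
summaries for the pairs that were not excluded.

## The genetic model

* **Founders** are drawn under Hardy–Weinberg equilibrium: at each locus
  two alleles are sampled independently from the population frequencies.
* **Transmission** follows Mendel's laws: a child receives one uniformly
  chosen allele from each parent, independently across loci.
* **No mutation**: a child allele is always carried verbatim by a parent.
  This is deliberate — the study isolates the risk created by relatedness,
  and reports *accumulative* non-exclusion rates (at most *k* mismatches)
  so a reader can overlay any mutation-tolerance policy afterwards.
* **No linkage, no substructure**: loci are independent and no
  co-ancestry (theta) correction is applied.

The simulated pedigree is the minimal one realizing all seven evaluated
relationships. Founders are the paternal grandparents I and J, the mother
F, the husband N of the father's sister, a second partner S of the
father, the mother J2 of the half-sibling's reference child, and a random
man X. The grandparents have children E (the true father), D (aunt) and K
(uncle); E and F have children B and C; N and D have R (a cousin: the son
of the father's sister); E and J2 have M; E and S have W (M's paternal
half brother). Each alleged father is tested against child B with mother
F, except the half-sibling scenario, which tests W against M with mother
J2. `scenario_pairings()` lists the role table.

## Exclusion rules and non-conformity tables

At one locus, with the alleged father's allele set $G_{AF}$ and the
child's $G_C$:

* **Duo**: excluded iff $G_{AF} \cap G_C = \emptyset$ (the standard
  motherless rule, with no homozygosity refinements).
* **Trio**: the *obligate paternal alleles* are deduced from mother and
  child — a homozygous child $aa$ obligates $a$; a heterozygous child
  $ab$ obligates the allele the mother does not carry, or both when she
  carries both. The man is excluded iff he carries no obligate allele.
  Because the obligate set is a subset of the child's alleles, duo
  exclusion implies trio exclusion, so per-pair trio mismatch counts
  dominate duo counts.

The number of excluded loci per pair, $k \in [0, L]$, is tabulated per
relationship and mode into three rows: per-$k$ counts, cumulative counts
(pairs with at most $k$ mismatches), and the cumulative proportion as an
**Agresti–Coull (modified Wald)** estimate. With
$z = \Phi^{-1}(1-\alpha/2)$ (the exact quantile, 1.959964 at
$\alpha = 0.05$, not 2):

$$\tilde n = n + z^2, \qquad \tilde p = \frac{x + z^2/2}{\tilde n},
\qquad \mathrm{halfwidth} = z\sqrt{\tilde p(1-\tilde p)/\tilde n}.$$

The reported rate is the *adjusted center* $\tilde p$, not the raw
proportion $x/n$ — which is why a relationship with zero non-excluded
pairs out of 10 000 still reports 0.02 ± 0.03 % rather than zero, and why
the parent rows read 99.98 ± 0.03 % rather than 100 %. Values are kept
unrounded internally; formatting rounds to two decimals, half away from
zero.

## Paternity index and probability of paternity

Per locus, the paternity index compares the probability of the child's
genotype under "tested man is the father" against "a random man is the
father". With population frequencies $p$:

* **Duo**: the numerator marginalizes the untyped mother over population
  frequencies while the tested man transmits one of his two alleles
  uniformly; the denominator is the Hardy–Weinberg probability of the
  child's genotype. For example, father $ab$ and child $ab$ give
  $(p_a+p_b)/(4p_ap_b)$.
* **Trio**: both numerator and denominator condition on the mother
  transmitting one of her alleles uniformly; the numerator lets the
  tested man transmit uniformly, the denominator draws the paternal
  allele from the population. For example, mother $aa$, child $ab$,
  father $b\cdot$ gives $1/(2 p_b)$ per father copy of $b$.

Excluded loci carry PI $= 0$. The combined LR is the product over loci,
so a single excluded locus annihilates it; log LR (base 10 throughout) is
therefore defined only for zero-mismatch pairs, and the LR summaries are
computed exactly over the pairs counted in the $k = 0$ column of the
exclusion tables. The posterior probability of paternity is
$W = 100 \cdot LR\pi/(LR\pi + 1 - \pi)$ with a flat prior $\pi = 0.5$ by
default (exposed as a parameter).

LR summaries report min, max and mean log LR with a *t*-based confidence
half-width of the mean, $t_{1-\alpha/2,\,n-1}\,s/\sqrt{n}$. (Printed
report tables of this kind sometimes label that column "standard
deviation ($\alpha = 0.05$)"; a plain standard deviation cannot reproduce
such tables — with two pairs at log LR 2.8206 and 3.2468 the label value
2.7075 is only recovered by the $t(1)$ half-width, which is why the field
is named `ci_half_width` here.) With one non-excluded pair the half-width
is undefined; with none, all statistics are absent — matching how such
report rows print "-".

## The synthetic frequency generator

Real casework panels (e.g. 15-locus identification kits) have published
population frequency tables; the pipeline accepts any such table as a
`locus,allele,frequency` CSV. For self-contained operation,
`generate_synthetic_frequencies()` draws a stand-in panel: per locus, an
allele count uniform on 8–15 and a symmetric Dirichlet(1) frequency
vector, floored at $10^{-4}$ and renormalized. The defaults were chosen
once as what a forensic geneticist would call realistic for such kits:
8–15 alleles per locus spans common autosomal STR panels, Dirichlet(1)
(uniform on the simplex) yields expected heterozygosities around
0.78–0.88 (panel means near 0.83), and the floor prevents zero-frequency
alleles that would make paternity indices unbounded. Allele labels are
opaque tokens; no computation interprets them as repeat counts.

What the synthetic panel does **not** emulate: the exact heterozygosity
profile and allele-frequency shape of any real population, linkage
between loci, or population substructure. Consequently the *absolute*
non-exclusion rates under a synthetic panel differ from those obtained
with a specific population table (more informative panels give lower
rates); what is invariant, and what the test suite asserts, is the
structure — true parents never excluded, trio at least as strict as duo,
and the risk ordering sibling ≫ {grandparent, uncle, half sibling} ≫
cousin ≫ random man. Reproducing published headline rates for a specific
population (e.g. ~19 % sibling duo non-exclusion) additionally requires
that population's frequency table, supplied via `freq_file =`; this is an
optional user-run check, since such tables are typically distributed in
the population-genetics literature rather than bundled.

## Randomness and reproducibility

A single master seed governs a run. `simulate_population()` derives one
substream seed per family from the master seed, so family *i* is
identical whether 1 or 10 000 families are simulated, and results are
invariant to evaluation order. `run_study()` derives separate sub-seeds
for panel generation and population simulation. Identical seeds give
byte-identical rendered reports (the run log, which carries timings, is
the only non-deterministic output file).

## Numerical choices and degenerate inputs

* Exact normal quantile in the Agresti–Coull formula; exact *t* quantile
  in LR summaries.
* Reporting rounds half away from zero to 2 decimals; all internal
  statistics are unrounded.
* A mother–child Mendelian incompatibility inside a trio evaluation
  raises an error: it cannot occur in a mutation-free simulation, so it
  signals a pipeline bug or inconsistent user input rather than a case to
  be scored.
* `n_families = 1` and single-locus panels are supported throughout; LR
  summaries with 0 or 1 non-excluded pairs degrade as described above.
* Very large combined LRs are converted to posteriors on the log scale,
  saturating cleanly at 100 % instead of overflowing.

## Validation strategy and problem sizes

The test suite validates every computational rule against an independent
route: exclusion rules and paternity indices against exhaustive
enumeration over all genotype configurations at 2–4-allele loci;
per-locus sharing rates for all six non-parent relationships against a
pedigree enumeration oracle (within 3 binomial standard errors at
n = 10 000 families on a single small locus); the vectorized study
kernels against the per-genotype functions; and the report arithmetic
against a published 15-locus, 10 000-family study's printed tables, which
rebuild cell-for-cell from their per-k counts. The full-scale default
study (10 000 families, 15 loci, 7 relationships, both modes) is run once
in the suite; it completes in well under two minutes on a single CPU.

## Limitations

No mutation model (by design), no silent/null alleles, no theta
(co-ancestry) correction, no sex-linked markers, no linkage. The package
evaluates the seven fixed pedigree relationships above; arbitrary
relationships would require extending the pedigree and the scenario
table.
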