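---
title: "Methods: disproportionality screening of FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`faersignal` implements an end-to-end pharmacovigilance screen of the FDA
Adverse Event Reporting System (FAERS), organised around the post-marketing
safety question for mirabegron, a β3-adrenergic agonist used in overactive
bladder: which adverse-event terms are reported disproportionately often with
the drug, how are the reports characterised clinically, how quickly after
exposure do events arise, and do the signals persist within strata of weight,
region, and co-medication. All statistics run identically on real FAERS
quarterly extracts and on the package's synthetic generator, which plants
known relative risks so that every stage is testable offline.

# Case curation

**Deduplication.** FAERS stores every version of a case. Following the
FDA-recommended rule, among records sharing a `CASEID` the version with the
largest `FDA_DT` is retained, and among ties the largest `PRIMARYID`.
Both comparisons are on numeric magnitude — identifiers are kept as strings
(leading zeros occur) but never compared lexicographically. Records lacking a
`CASEID` are retained as singleton cases and counted, which is conservative:
dropping them would silently shrink the denominator.

**Name matching.** Verbatim FAERS drug names carry dose and form suffixes
("MIRABEGRON 50 MG TABLET"), so the matcher looks for any configured pattern
(defaults: MIRABEGRON, BETMIGA, BETANIS, MYRBETRIQ) as a case-insensitive,
word-bounded substring of `DRUGNAME` or `PROD_AI`. Word-bounding (token
boundaries at non-alphanumerics) avoids false hits such as MIRTAZAPINE under
a plain substring rule.

**Cohorts.** The target cohort is deduplicated cases where a matched drug has
role PS (primary suspect) and the reporter occupation is a healthcare
profession (MD, PH, OT by default). We read "exclusively documenting the drug
as PS" as *the target appears with role PS*; a strict mode additionally
requiring that no other drug carries PS is available behind a flag, since
the two readings differ and the looser one matches the stated inclusion
criterion. The comparator is every other deduplicated case under the *same*
reporter filter, so numerator and denominator cohorts are curated
identically; a flag switches to the unfiltered background for sensitivity
analysis.

**SOC exclusions.** Events in four MedDRA system organ classes generally
unrelated to drug action — injury/poisoning/procedural complications, product
issues, surgical and medical procedures, social circumstances — are removed
from both cohorts before screening, with removal counts logged.

**PT normalisation.** FAERS preferred-term casing is inconsistent across
quarters; all PT text is trimmed, whitespace-collapsed and sentence-cased
before any counting, so counts cannot split across case variants. PTs absent
from the user-supplied PT→SOC mapping resolve to `UNMAPPED`; they take part
in PT-level screening but not SOC-level aggregation. MedDRA itself is
licensed and is not shipped; a toy ontology (~100 PTs, 15 SOCs) supports the
examples and tests, and only the primary SOC of a PT is used.

# Disproportionality statistics

Counting is **report-level**: one deduplicated report contributes at most
once per distinct event term, giving the 2×2 table

|            | event | no event |
|------------|-------|----------|
| target     | a     | b        |
| comparator | c     | d        |

with `a + b` the target cohort size and `N = a + b + c + d`.

**ROR.** The reporting odds ratio is `ad/(bc)` with the Wald interval
`exp(ln ROR ± z·√(1/a + 1/b + 1/c + 1/d))`. If any cell is zero the
Haldane–Anscombe correction (add 0.5 to all four cells) is applied first and
flagged. Tables with an empty margin are tagged undefined rather than
returning NaN. A term is ROR-positive when the 95% CI lower bound exceeds 1
and `a ≥ 3`.

**BCPNN information component.** The raw IC is
`log2(a·N / ((a+b)(a+c)))`, the log2 ratio of observed to expected
co-reporting probability under independence. The Bayesian model places
independent Beta posteriors on the cell probability `p11` and the margins
`p1.`, `p.1`, with the standard prior pseudo-counts γ11 = α1 = β1 = 1,
α = β = 2 and the cell prior total γ tied to the margins so the prior IC is
centred at zero. `IC025 = E(IC) − 2√V(IC)`; a term is IC-positive when
IC025 > 0, and *of interest* when both criteria hold.

Three variance models are provided:

* `bate1998` (default): E(IC) and V(IC) from the **exact** log-Beta posterior
  moments, `E[ln X] = ψ(u) − ψ(u+v)` and `Var[ln X] = ψ′(u) − ψ′(u+v)`
  (digamma/trigamma). This is the same Bayesian model as the classic
  formulation, evaluated without series truncation; it tracks the posterior
  2.5th percentile to within ~0.16 bits across a broad suite of tables with
  `a ≥ 3`.
* `bate1998_delta`: the classic first-order series approximation of the same
  moments, kept for reference. For very small `a` it can sit ~0.4 bits above
  the true posterior percentile, which is why it is not the default.
* `montecarlo`: direct sampling of the posterior (independent Beta draws),
  IC025 as the empirical 2.5th percentile. This is the validation oracle for
  the closed forms and is also exercised independently in the test suite.

**A note on published IC columns.** In the published mirabegron screen the
printed gap IC − IC025 is nearly constant (≈1.66 bits) across terms whose
counts range from 3 to 817. No posterior-variance construction reproduces
that: the credibility interval must tighten as `a` grows. The printed column
appears to track `log2(ROR)` with a fixed offset. We therefore implement the
standard BCPNN formulations and do not reverse-engineer an undocumented
constant; our IC025 is a genuine shrinkage bound and will differ from such
printed columns, while the dual decision rule (CI lower bound > 1 with
`N ≥ 3`, IC025 > 0) is unchanged.

**Multiplicity.** No multiple-testing adjustment is applied, matching common
practice for hypothesis-generating disproportionality screens; signals are
not causal findings. An adjusted column can be enabled downstream but is off
by default.

**Ranking.** Output is ordered by SOC, then descending ROR ("signal
intensity"), with ties broken by descending `a` and then term name so runs
are bit-for-bit reproducible.

# Descriptive conventions

Percentages are computed against the cohort size and rounded **half-up** to
two decimals (base R's `round()` is half-to-even, which does not match how
safety tables are conventionally printed). Ages floor to completed years
before banding into ≤17, 18–64, 65–85, ≥86, Unknown; weights band into
<50, 50–100 (inclusive at both ends), >100 kg. Unknown age units with values
in 18–120 are treated as years, the overwhelmingly common data-entry
omission. Daily dose is defined only for mg units with a known per-day
frequency multiplier (QD/BID/TID/QID/QOD) and binned into the conventional
12.5/25/25–50/50/75/100/150 mg/day categories. Medication duration is the
calendar-day difference `end − start` (same-day therapy = 0 days) at day
precision only; bins are 0–30, 31–60, 61–90, 91–180, 181–360, >360, with
day 361 in the open bin so every duration is binnable (published tables
sometimes label that bin ">361", leaving day 361 unassignable — we do not
reproduce the gap). The serious-outcome panel counts each case at most once
per outcome code; since one case can carry several codes, that panel is not
exhaustive and is documented as such.

# Time-to-onset

Onset time is the number of days from the earliest day-precision therapy
start linked to the matched PS drug to the day-precision event onset date.
Partial or missing dates make a case non-evaluable (counted), and negative
intervals are excluded with their own counter rather than clamped. The
median and IQR use the linear-interpolation quantile convention (type 7, the
default in most scientific software; the convention used in the original
analyses is not stated). Bins match the duration bins, with 0–30 inclusive at
both ends.

# Subgroups

A subgroup specification restricts *both* cohort arms to the stratum
(within-stratum 2×2); comparing a stratified numerator against the global
background is available via configuration but is not the default, because a
within-stratum comparator controls for stratum-level reporting differences.
Weight strata use the descriptive bands; continent strata resolve the
reporter country (falling back to the occurrence country when absent)
through a user-suppliable country→continent table; concomitant strata select
reports co-listing a word-bounded match of the co-drug pattern in any
non-target role, optionally restricted to specific role codes (e.g. strictly
concomitant C, or including SS — both selections are one flag apart, since
published analyses rarely state which was used). The trivial stratum
reproduces the global screen bit-for-bit, which the tests assert.

# The synthetic generator

The generator emulates the statistical structure the screen assumes, not
real FAERS marginals. Defaults — fixed as the package's study conditions —
are:

* 2,000 target-cohort reports (HCP reporter, target drug PS), 500 extra
  non-HCP target reports, 300 reports with the target drug in a non-PS role,
  and 20,000 background reports. Desk-scale sizes: the real screen involves
  millions of background reports, which neither tests nor examples need.
* a ~50-term PT vocabulary with background probabilities 0.001–0.04,
  including PTs in the four excluded SOCs and one deliberately unmapped PT;
* planted signals: relative risk 5 on a PT with background probability 0.01
  (expected `a ≈ 100`), plus RR 3 and RR 2 on two further PTs. Target-drug
  PS reports draw each PT with probability `min(1, RR·p)`; everything else
  uses `p`. Note the estimand recovered by the ROR is the planted *odds*
  ratio `RR(1−p)/(1−RR·p)` (≈5.21 for RR 5 at p = 0.01);
* duplicate-version rate 0.15, with a fifth of duplicates tying on `FDA_DT`
  so the PRIMARYID tie-break is exercised;
* lognormal onset times with meanlog log(25) and sdlog 1.63, giving median
  25 days and an IQR of roughly 7–75 days, plus a 2% planted rate of
  negative intervals (event before start, a real FAERS data error);
* missingness typical of FAERS demographics (event date 35%, therapy start
  30% plus 10% month-precision, weight 80%, age 40%, dose 55%);
* demographics roughly matching the published cohort margins (60% female,
  elderly-skewed ages, US/JP/GB-dominated countries), and a co-drug pool
  whose probabilities are ordered aspirin > atorvastatin > solifenacin > …
  so concomitant ranking has a known truth;
* FDA receipt dates spread over 2022Q1–2023Q3, yielding seven quarterly
  file bundles (event and therapy dates may precede the window).

Everything is driven by a single seed; `regenerate_check()` asserts
byte-identical regeneration. Prefix stability is *not* promised: changing a
size parameter reshuffles subsequent draws.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: the ~25k-term PT vocabulary and its heavy-tailed
marginals, drug-specific reporting waves and secular trends, correlated
event co-reporting (terms are drawn independently), masking by competing
signals, country-specific coding habits, and free-text drug-name noise
beyond the bundled spelling variants. Conclusions about operating
characteristics on real FAERS data require the full-scale run on the real
quarterly archives.

# Numerical and engineering choices

* Dates parse totally: 8/6/4-digit strings give day/month/year precision,
  anything else (including month 13) precision "none"; downstream arithmetic
  requires day precision rather than imputing.
* Malformed table rows (wrong field count) are excluded but counted, so rows
  in = rows parsed + rows malformed, per table. Child-table rows whose
  report identifier is absent from DEMO are counted as orphans and excluded.
* All randomness in the Monte-Carlo IC model uses the caller's RNG stream;
  the generator seeds explicitly.
* Problem sizes in the test suite are chosen so the whole suite runs in a
  few minutes: 100 replicates at the default generator size for the
  operating-characteristics checks, 200k posterior draws per Monte-Carlo
  oracle evaluation, and a 110k-report single replicate for the
  convergence check of the planted odds ratio (±15%).

# Limitations

Disproportionality on spontaneous reports is hypothesis-generating: no
incidence, no causality, reporting bias throughout. The package does not
implement PRR, EBGM/MGPS or shrinkage-regression methods, does not link
duplicate cases beyond the FDA rule (no probabilistic record linkage), does
not read the FAERS XML dialect or pre-2012Q4 legacy schemas beyond the
aliases actually needed, and ships no MedDRA content. The expected-reaction
annotation is a fixed 23-term list for the mirabegron label; for other drugs
supply your own.
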