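---
title: "Mining ejection fraction from clinical text: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining ejection fraction from clinical text: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efminer)
```

## The problem

Hospital registers typically code congestive heart failure (HF) as a single
diagnosis, although HF with reduced (HFrEF, EF < 40%), mildly reduced
(HFmrEF, 40–49%) and preserved (HFpEF, ≥ 50%) ejection fraction are
clinically distinct. The quantitative EF lives in narrative echo reports.
`efminer` implements a deliberately simple, fully auditable rule engine for
extracting those EF values, a guideline-based subtyping rule that adds
NT-proBNP, validation metrics against chart review, and an age-scale Cox
model for subtype-specific mortality. This vignette records the method, its
assumptions, and the design choices made where the procedure was genuinely
open.

## The mining procedure and its assumptions

Text is split into sentences at `.`, `!`, `?` and newlines, except that a
period flanked by digits (decimal values, Finnish-style dates such as
`12.5.2019`) does not terminate. A sentence enters value parsing only when
it contains a trigger: `EF` matched case-sensitively at word boundaries (so
"LEFT" or "chef" never fire), or `ejection fraction` case-insensitively.

Parsing is staged:

* **numeric** — a two-digit integer part with optional decimals (`.` or
  `,`, the latter for the decimal comma) whose next token is `%` or a
  percent word. Two digits are a modelling assumption, not an accident:
  single-digit EF is below any plausible measurement and three digits would
  exceed 100, so both are treated as non-EF numbers. The search runs
  rightward from the trigger; constructions like `35% EF` are caught by
  also scanning the two tokens immediately left of the trigger
  (`numeric_left_context`, on by default, can be disabled in the lexicon).
* **range** — hyphen-separated two-digit pairs with a percent marker on
  either or both numbers. The procedure that motivated this package finds
  ranges but never states how they collapse to one number; we resolve a
  range to its **midpoint**, the symmetric choice, and keep both endpoints
  in the audit trail. A matched range suppresses numeric sub-matches of its
  own digits, so `EF 35-40%` is one candidate, not three.
* **worded** — only when no numeric or range candidate in the sentence was
  accepted, a longest-phrase-first search maps worded descriptions to
  percents: "preserved" → 50, "mildly reduced" → 45, "reduced" → 39,
  anchored to the 2016 ESC bands. "mildly reduced" shadows its substring
  "reduced" by the longest-first rule. The shipped extras
  ("severely reduced" → 25, "normal" → 60) are artifact-defined defaults
  chosen as clinically conventional round numbers; they are marked as such
  in the lexicon file and can be removed. Lexicons are external YAML so a
  production vocabulary in another language can be substituted wholesale.

Two quality checks then run on every candidate. A candidate overlapping a
date-shaped token (`d.m.yyyy`, `d/m/yyyy`, `d.m.`, `d.m.yy`, or a
two-digit number followed by a four-digit year) is rejected as
`date_masquerade`; the practically reachable case is a two-digit year
fragment of a `d.m.yy` date followed by a percent sign. If the sentence
contains a past-reading qualifier ("a year ago", "years ago",
"previously", or the pattern "in *yyyy*"), **all** candidates in that
sentence are rejected as `past_reading`. The scope is the sentence:
cross-sentence temporal reasoning is out of scope, as is negation handling
and any statistical NLP. Rejected candidates are retained with reason codes
rather than dropped — the validation experience behind this design showed
that reviewing misclassified cases requires seeing what the miner almost
did.

Offsets are 0-based and half-open everywhere, and extraction is
deterministic: the same note and lexicon always give the same mentions.

## From mentions to a cohort

Accepted mentions are averaged within each patient–calendar-day (we
average per day across notes, not per note; same-day duplicate reports are
the common case the averaging exists for). Daily means outside the closed
band **[10, 90]** are removed; the bounds are applied after averaging,
following the published flow of the procedure, and the boundary values are
kept because exclusion is stated strictly ("< 10% or > 90%"). Averaging an
incorrect with a correct same-day value is a known error mode; `n_mentions`
and the audit trail expose multi-mention days for review, and no automatic
adjudication is attempted.

One **index EF** per patient feeds subtyping. The selection rule was not
stated in the source procedure; the default is *latest* (subtype is a
statement about current clinical state), with *earliest* and
*nearest-to-date* (ties to the earlier sample) available.

Subtyping: EF < 40 → HFrEF; 40 ≤ EF < 50 → HFmrEF (the half-open band
keeps a daily mean of 49.5 mildly reduced); EF ≥ 50 splits on NT-proBNP at
125 ng/l. Two boundary decisions deserve emphasis:

* **Units.** The methods text we follow prints the threshold as
  "125 ng/ml", but the accompanying cohort table reports proBNP in ng/l
  (a no-HF mean of 77 is only sensible in ng/l) and the ESC rule-in
  threshold is 125 ng/l = 125 pg/ml. We treat "ng/ml" as a typo and use
  **ng/l** as the canonical unit throughout.
* **proBNP exactly 125.** The source rules overlap ("≤ 125" normal,
  "≥ 125" HFpEF). We resolve 125 → NoHF, i.e. elevation is strictly
  above threshold.

proBNP pairing (nearest sample within ±365 days, ties earlier) is an
artifact convention — the source does not state one. Patients with EF ≥ 50
and no paired proBNP are labelled `Indeterminate` rather than silently
classified; they are excluded (with logged counts) from validation and
survival, mirroring a study design in which proBNP was only required for
HF cases. Creatinine is required by default (eGFR is a model covariate);
eGFR uses the CKD-EPI 2009 creatinine equation without the race term.

## Validation metrics

The confusion matrix is oriented rows = algorithm, columns = gold
standard. Per-class metrics use the one-vs-rest collapse, with "HF-any"
pooling the three HF subtypes; undefined ratios (0/0) are reported as
missing, never 0. Display rounding is half-up to integer percent, matching
the precision of published validation tables; full precision is retained
internally. EF agreement is reported three ways: exact, within ±5 EF
percentage points (interpreted as absolute points, not relative 5%), and
same ESC band.

## Survival model

Cox proportional hazards with **age as the time scale**: each patient
enters the risk set at their entry age (left truncation) and leaves at
death or censoring. The risk-set construction was not spelled out in the
source; left truncation at baseline age is the standard construction and
is what `survival::coxph(Surv(entry, exit, event) ~ ...)` fits. Ties use
the Efron approximation (the common default; a `ties` argument exposes
Breslow, under which exact invariance properties such as
duplicate-the-data hold). Covariates are sex, eGFR and five comorbidity
flags. Proportionality is checked with scaled Schoenfeld residuals against
event age (identity transform) and the standard per-term trend test.

## The synthetic world

`gen_config()` defaults state the world the generator emulates, chosen
once from the published cohort descriptives and held fixed:

* subtype mix 3.4% / 1.4% / 6.2% / 89.0% (HFrEF/HFmrEF/HFpEF/NoHF);
* per-subtype age means/SDs (67.9±14.6, 68.8±13.1, 70.8±14.6, 57.3±18.1),
  sex ratios and comorbidity prevalences from the same descriptive table;
* EF drawn uniformly per band: HFrEF 15–39, HFmrEF 40–49, HFpEF/NoHF
  50–75;
* proBNP log-normal per subtype with location/scale giving means of the
  observed order of magnitude, capped at ≤ 125 ng/l for NoHF and floored
  above 125 for HFpEF so generated labels are internally consistent (a
  generative spec, not an estimate — the published summaries are not a
  distributional model);
* proBNP missing in 10% and creatinine in 5% of patients;
* survival from a Gompertz baseline `h0(a) = 4.5e-5 * exp(0.09 a)` per
  year of age (hazard ≈ 1%/year at age 60 for the reference group, a
  realistic all-cause figure), multiplied by subtype hazard ratios
  2.63 (HFrEF), 1.91 (HFmrEF), 2.28 (HFpEF) — the published point
  estimates used as generative truth, since the original individual-level
  data are access-restricted — plus modest sex, eGFR and comorbidity
  effects; administrative censoring 5 years after entry.

Each patient receives one index note from a clean template (numeric,
range, worded, or two same-day readings whose mean is the truth), chosen
by renormalising the clean part of `template_mix`; each distractor entry
of the mix is the per-patient probability of an additional distractor note
(past reading, date lookalike, non-EF percentage). When the clean mass is
zero, patients get a single distractor note instead — that is what a
"distractor-only corpus" means in the tests. All randomness flows from one
seed.

What a green end-to-end test establishes: on *unambiguous, planted*
sentences the miner has recall and precision 1, never accepts a date or a
past reading, and reproduces the generative subtype wherever the required
labs exist. What it does not establish: performance on real clinical
prose — abbreviation soup, typos, Finnish morphology, negation,
copy-forward text. The published validation against chart review (78%
exact EF agreement, 87% within 5 points) characterises that gap; it cannot
be recomputed here and no synthetic number stands in for it.

## Numerical and degenerate-input choices

* Half-up rounding (`round_half_up()`) for display percents; all
  comparisons in code use full precision.
* Empty text, trigger-free notes and empty files yield empty, correctly
  typed tables, not errors.
* `daily_mean()` refuses rejected mentions (filtering is the caller's
  explicit step); `assign_subtype()` refuses EF outside [10, 90] as
  pipeline misuse.
* Lab unit conversion is idempotent (canonical units convert by 1);
  creatinine mg/dl converts by 88.42.
* Cox fits error on zero events, inestimable terms or apparent separation
  (|log HR| > 15) instead of returning silently absurd estimates.

## Known limitations

No negation or uncertainty handling; no cross-sentence temporal
reasoning; no longitudinal EF trajectories (an index EF is a snapshot);
no competing risks or time-varying covariates in the survival model; the
shipped lexicon is English while the motivating deployment was Finnish —
the lexicon file is the substitution point.
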