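---
title: "Coding voice-assistant interaction logs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding voice-assistant interaction logs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svacoder)
```

## The coding model

`svacoder` codes time-stamped transcripts of older adults' interactions
with a smart voice assistant into twelve routine categories. The unit of
analysis is the **episode**: one completed (or attempted) routine,
regardless of how many utterances it took. This matters because speech
patterns in older cohorts — repetitions, corrections, confirmations — mean
a single routine frequently spans several commands, and because multi-turn
skills such as the Akinator guessing game are *designed* to span many
turns. Counting utterances would systematically over-count exactly the
interactions that are most characteristic of the population.

The pipeline makes three passes over a participant's log:

1. **Chronological normalization.** Records are sorted by timestamp
   (ties keep input order, preserving command/response adjacency) and
   assigned to weeks. Week $k$ covers the half-open calendar interval
   $[\mathrm{anchor} + 7(k-1), \mathrm{anchor} + 7k)$ days, anchored at
   midnight of the participant's first interaction date unless an explicit
   anchor is supplied. Assignment depends only on the calendar date, so it
   is order-independent and reproducible; anchoring per participant keeps
   week 1 meaningful for rolling enrollment.
2. **Lexicon matching.** Utterances are lowercased, stripped of
   punctuation (apostrophes inside words survive), split on whitespace,
   and a leading wake word is dropped. A category matches when one of its
   keyword phrases occurs as a contiguous token run. When several
   categories match, a fixed precedence order decides; named skills
   (Big Sky, Akinator, Five Minute Morning Meditation, Riddle) outrank
   generic categories (Weather, Music) so that "open big sky" is coded as
   the skill and not as weather.
3. **Episode segmentation.** A matched utterance opens an episode. A
   later user utterance *extends* the open episode iff it arrives within
   `gap_seconds` of the previous user command **and** (a) matches the
   same category, (b) consists solely of continuation tokens ("yes",
   "no", "i don't know", ...), or (c) matches nothing but shares at least
   one token with the previous command — the repeated-or-corrected-command
   case, implemented with the `find_same_words` set operator. An utterance
   matching a *different* category always closes the open episode and
   opens a new one, whatever the gap. Unmatched, non-continuation
   utterances outside any episode are dropped: a stray "yes" with no open
   session has no codable category. Assistant turns never open or extend
   episodes; they only decide completion.

An episode is **completed** when at least one assistant response fell in
its span (opening command through `gap_seconds` after the last command,
capped at the next episode) and none of those responses contains a
configured error phrase. Crosstabs count all episodes by default;
`completed_only = TRUE` (or `--completed-only`) restricts to completed
ones. Whether incomplete attempts belong in the counts is a study-level
choice, so the package exposes it rather than deciding it.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `gap_seconds` | 60 | seconds | "temporally continuous" is not a physical constant; 60 s accommodates slow speech and assistant turn-taking while separating distinct routine runs. Exposed everywhere; the episode count is monotonically non-increasing in it. |
| lexicon keywords | shipped defaults | — | a reconstruction from the category labels and routine examples; study codebooks are rarely published verbatim, so every list, the precedence, the wake words, continuation tokens and error phrases are overridable via a YAML file. |
| `anchor_date` | first interaction date | calendar date | per-participant anchoring; override to a common protocol start when the study design has one. |
| rounding | half-up, 2 decimals | — | reported percentages follow the half-up convention used in published agreement tables; base R's banker's rounding would turn e.g. 0.125 into 0.12. |

## Reliability conventions

Percent agreement is $100 \cdot n_{agree}/n$; Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$ with expected agreement from the product
of the two coders' marginals over the union of observed codes. An uncoded
case counts as its own level ("none") in both statistics: either coder can
legitimately leave a case uncoded, and silently dropping those cases would
change $n$. Discrepancy labels (program error, human error, definition
difference) are adjudication *input* — the product of the human-coder /
programmer discussion — not something the package infers; it validates
that every disagreement carries one and tabulates counts and percentages
of all cases. Percentages are always recomputed from counts rather than
transcribed, which also resolves transposition slips in secondary
reporting.

## Factor analysis

The factor module answers "do two coding methods induce the same
structure?". The observation unit is the **participant-week**: one row per
participant per observed week, twelve count columns. A cohort of a handful
of participants cannot support a 12-variable analysis on per-participant
totals; participant-weeks are the only unit that makes the fit
well-posed at realistic cohort sizes, and weekly counts are what the
crosstab stage already produces. Per-participant totals remain available
(`per_participant = TRUE`) for sensitivity analysis.

The fit is principal components on the Pearson correlation matrix (hence
scale-free in the raw counts), Kaiser retention (eigenvalue strictly
greater than 1), unrotated loadings $v_j\sqrt{\lambda_j}$, then varimax
rotation of the retained block. Varimax is implemented as Kaiser's
classical pairwise planar-rotation sweeps with row normalization
(tolerance $10^{-6}$ on the rotation angle, at most 100 sweeps);
communalities are preserved by construction, and the test suite
cross-checks the attained criterion against `stats::varimax`. Eigenvalues
and variance proportions ($100\lambda_j/12$) are reported pre-rotation;
each rotated column is sign-flipped so its largest-magnitude loading is
positive, removing the sign indeterminacy. Solutions are compared by
retained-factor count and, when counts agree, by greedy matching of factor
pairs on absolute Tucker congruence
$\phi(x,y)=\sum x y/\sqrt{\sum x^2\sum y^2}$.

Degenerate inputs fail loudly: fewer than 3 observations, or a constant
column (a category never observed varies nowhere and has no correlation),
are errors naming the offender rather than silent drops.

## The synthetic generator

No public corpus of older adults' assistant transcripts exists, so the
package ships a seeded generator that emulates the features the coding
rules must handle: per-participant multi-week logs; episode counts drawn
per participant-week and category from Poisson distributions; opening
commands drawn from per-category templates; restatements of the command
with probability `repetition_rate`; Akinator sessions extended by a
Poisson number of yes/no continuation turns; interleaved assistant
responses, a configurable fraction of which carry an error phrase; and
orphan continuations plus unmatched chatter under `corruption = TRUE`.

Defaults describe a study-like deployment: 7 participants for 12 weeks,
category rates (episodes per participant-week) of 1.5, 0.8, 0.6, 0.6,
2.0, 0.9, 1.7, 1.0, 0.5, 0.5, 1.4, 0.3 in code order — greetings, music
and weather daily-ish, games and settings occasional — chosen so the
cohort produces on the order of a thousand coded interactions, the scale
at which manual-versus-automated comparisons become interesting;
`repetition_rate` 0.25; mean game length 4 turns; within-episode gaps of
3–30 s; at least 180 s between episodes; 10% assistant failures.

Two properties make the generator an exact oracle rather than a fuzzer.
Templates are validated at generation time to code as exactly their own
category, and every within-episode gap is strictly below every
between-episode gap, so for any threshold placed between the two the coder
must recover the generated truth *exactly* — categories, weeks, command
counts and completion flags. The test suite asserts that equality, not
approximate agreement.

What the generator does **not** emulate: free conversation, misrecognized
speech, paraphrases that share no token with any keyword, overlapping
routines, or time-zone/daylight clock artifacts. Passing the recovery
tests therefore shows the segmentation rules are implemented correctly,
not that the default lexicon would reach any particular agreement level on
real transcripts — that depends on a study's codebook, which is exactly
why the lexicon is data, not code.

## Numerical and interface choices

- Timestamps parse as ISO 8601 (`T` or space separator, seconds optional),
  are treated as local to the participant, and are compared as instants;
  no time-zone arithmetic is attempted.
- Identical timestamps keep input order (stable sort), preserving the
  dialogue order of command/response pairs exported with coarse clocks.
- The crosstab's XML dialect nests weeks under categories with a trailing
  total per category, in fixed code order, and serialisation is
  byte-deterministic so exports can be diffed and golden-tested; parsing
  validates totals against column sums and rejects negatives.
- The participant count is never asserted: all summaries are data-driven.
  (Published descriptions of such cohorts sometimes disagree with
  themselves about N; nothing here depends on it.)
- CLI subcommands wrap the same functions; timings appear in the run
  manifest on stderr for efficiency narratives but are never assertions,
  being hardware-dependent.

## Problem sizes used in the test suite

Unit and property tests run on logs of at most 20 records (200+ seeded
cases against a brute-force run enumerator), synthetic cohorts of 2–7
participants over 2–12 weeks, a 500-cell Poisson goodness-of-fit check of
the generator, and factor fits at n = 300–1,000 observations — sizes at
which the closed-form oracles are exact and a full run stays in the tens
of seconds on one core.

## Known limitations

- Keyword matching is exact contiguous-token matching: no stemming,
  lemmatization, spelling correction or embeddings. A garbled command is
  only caught by the shared-token extension rule, and only inside an open
  episode.
- An episode's category is fixed by its opening utterance; a user who
  changes their mind mid-episode splits it, by design.
- "Contextual analysis" beyond keyword presence, precedence and the
  temporal rules is out of scope, as are speech-act labels, sentiment, or
  any cognitive-status inference from text.
- The shipped lexicon is a starting point, not a validated codebook;
  studies should supply their own via `load_lexicon()` and report it.
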