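---
title: "Reconstructing diurnal care-team networks from EHR activity metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing diurnal care-team networks from EHR activity metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carenet)
```

## The problem

Care of paediatric trauma patients is delivered by a multi-team system
(MTS): fluid, interdependent specialty teams (emergency department staff,
general paediatric surgery, neurosurgery, orthopaedics, intensive care,
allied professionals) whose composition changes with the time of day.
Direct observation of such systems is expensive and incomplete; the
electronic health record, however, passively captures a timestamped trace
of who acted on which patient when. `carenet` reconstructs collaboration
networks from that trace and asks how team organisation differs between day
(07:00–18:59) and night (19:00–06:59) shifts at three care locations: the
emergency department (ED), the general ward (floor), and the paediatric
intensive care unit (PICU).

Because raw EHR extracts of this kind are protected health data, the
package ships a seeded synthetic event-log generator that emulates the
*metadata structure* of such an extract — never clinical content — with
known, planted team structure. Every stage of the pipeline is exercised and
validated against that known truth.

## From activity records to a master event log

An activity record is one row of EHR metadata: encounter, timestamp,
activity type (note, procedure order, medication order, flow-sheet entry,
medication administration), the acting health-care professional (HCP) and
their generic role, and — for order-type records — the care location.
Preparation proceeds in five steps:

1. **Timestamp normalisation.** Timestamps are replaced by minutes from ED
   arrival (`t_norm`), preserving within-encounter order. Records
   timestamped before arrival are registration artifacts and are dropped
   (with a logged count) rather than clamped, since every downstream
   contract assumes `t_norm >= 0`.
2. **Exclusions.** System-initiated records, records by student roles, and
   records without a full complement of data carry no accountability for
   care and are excluded; every exclusion carries a machine-readable
   reason, and kept plus excluded always partition the input.
3. **Location inference.** Notes and flow-sheet entries lack a location; it
   is inferred from the encounter's admission/discharge/transfer (ADT)
   timeline under a half-open `[start, end)` convention, clamping to the
   last interval for records documented after the final transfer.
4. **Functional-role resolution.** Collaboration is analysed at the level
   of *functional roles* (service-prefixed generic roles such as `ED_RN` or
   `Neurosurg_R`), not individuals. The service is resolved per role class:
   attendings, fellows, physician assistants and specialty nurse
   practitioners carry their service on their own notes, globally;
   residents and radiology technicians rotate, so their service is resolved
   per encounter as the modal service of the attending who cosigned their
   notes in that encounter (ties to the most recent note); nurses, unit
   nurse practitioners and allied professionals take the service bound to
   the modal location of all their activities (ties to the earliest
   occurrence, then lexicographic). HCPs without resolvable service are
   excluded, as are note/flow-sheet records of unit staff whose inferred
   location contradicts their base unit.
5. **Fan-out and shift labelling.** A note with a cosigning attending
   becomes two same-time events (author and cosigner); the note creation
   time is used as its event time, since sign-off may lag the work by
   hours. Every event is labelled with its shift number (0 at arrival,
   incrementing at each 07:00/19:00 boundary) and shift type, both pure
   functions of wall-clock time.

## Natural-break segmentation

Within a shift, activity arrives in bursts separated by quiet gaps. Events
are partitioned into *segments* wherever the gap between adjacent events
reaches a break interval; a gap exactly equal to the interval starts a new
segment. The interval is chosen on a 30–120 minute grid in 5-minute steps —
30 minutes being the assumed minimum lag between co-occurring real-world
activity and its registration — by two-class Jenks natural-breaks
optimisation: for each candidate boundary $c$ the pooled gaps split into
$\{g < c\}$ and $\{g \ge c\}$, and the goodness of variance fit

$$\mathrm{GVF}(c) = 1 - \frac{\mathrm{SSD_{within}}}{\mathrm{SSD_{total}}}$$

is maximised, ties broken towards the smallest candidate (the finest
segmentation consistent with the 30-minute floor). If all gaps are
identical the grid minimum is returned with a warning. Gaps are pooled
globally across the master log by default so that the day and night
segmentations remain directly comparable; a per-sublog mode
(`jenks_scope = "per_sublog"`) is available for sensitivity analysis.

## The working-closely-together metric

The shift is the unit of collaboration opportunity: roles involved in the
care of the same patient during the same shift *could* have worked
together; roles captured within the same segment *did* work closely
together. For each of the six sublogs (location × shift type), an
undirected edge is created among all pairwise combinations of roles within
each segment, and

$$w(a,b) \;=\; \frac{\#\{(\text{encounter, shift}) : a,b \text{ share a segment}\}}
                    {\#\{(\text{encounter, shift}) : a,b \text{ both involved}\}}$$

so that $w \in (0, 1]$, with $w = 1$ exactly when the pair co-segments in
every shift it shares. Both counts are scoped to the same sublog and the
same patient-shift, since opportunity is defined per patient per shift. A
pair co-segmented several times within one shift counts once. Roles never
co-segmented with anyone remain in exports as isolated nodes but are
excluded from reported node counts, which follow the convention of network
figures that show connected roles only.

## Threshold selection

Raw co-occurrence networks contain spurious edges. A shared-shift threshold
$t$ is swept from 2 to 20 on the raw `co_segment_shifts` counts; the first
sweep point already removes count-1 edges, whose total is reported
separately. The per-step number of edges removed is smoothed by locally
weighted linear regression (LOWESS, span `lowess_fraction`, default 0.5,
clipped at zero, and deliberately without robustness iterations — on a
19-point curve those would treat the initial removal spike, the very
feature the elbow is judged against, as an outlier and erase it), and the
elbow is the smallest $t$ from which the smoothed
rate stays at or below `elbow_epsilon` (default 0.10) times its maximum —
the point where further pruning removes a negligible number of edges. Two
degenerate cases are defined explicitly: an (approximately) constant rate
of change has no elbow structure and yields $t_{\min}$, and a rate that
never becomes insignificant yields $t_{\max}$ with a warning. Both LOWESS
span and $\varepsilon$ are declared assumptions exposed in
`threshold_config()`, and the full curve with the chosen elbow is always
written out (`*_threshold_curve.csv`, `plot()` method) so the selection can
be inspected visually, which is how elbow methods are ordinarily judged.
Thresholds are selected per sublog independently. Pruning keeps edges with
count at or above the elbow, drops newly isolated nodes, and leaves weights
unchanged.

## Overlapping link communities

Clinical roles belong to several teams at once, so communities are detected
on *edges*, not nodes. For edges $e=(i,k)$, $f=(j,k)$ sharing node $k$,
similarity is the weighted Tanimoto coefficient

$$S(e,f) = \frac{a_i \cdot a_j}{\lVert a_i\rVert^2 + \lVert a_j\rVert^2 - a_i \cdot a_j},$$

where $a_i$ is the weight vector from $i$ to its inclusive neighbourhood
and the self-entry $a_i(i)$ is the mean weight of $i$'s incident edges;
with uniform weights this reduces to the Jaccard index of inclusive
neighbourhoods. Edges are clustered agglomeratively with WPGMA (McQuitty)
linkage on $d = 1 - S$ — after merging $A$ and $B$, $d(AB, C) =
(d(A,C)+d(B,C))/2$ — so that edge weights inform community structure.
Non-adjacent edge pairs sit at distance 1, which also places disconnected
components side by side at the top of the dendrogram. Ties are broken by
the smallest canonical edge-pair key, making the dendrogram invariant to
input order.

The dendrogram is cut at the height maximising the partition density

$$D = \frac{2}{M} \sum_c m_c\,\frac{m_c - (n_c - 1)}{(n_c - 2)(n_c - 1)},$$

evaluated at every distinct merge height plus the all-singletons level,
with communities of two nodes contributing zero; ties go to the cut with
more communities. $D = 1$ exactly when every community is a clique spanning
its nodes. Clusters with at least two edges are reported as communities;
single-edge clusters are background, mirroring the reference behaviour of
ignoring trivial clusters. Node memberships are the communities among a
node's incident edges, and pie fractions give the proportion of its edges
in each community (plus background), always summing to one.

The cut criterion deserves one note: descriptions of this method sometimes
name modularity instead of partition density as the objective. Partition
density is the native objective of the edge-clustering algorithm and is
what this package implements; users comparing against other software should
check which criterion it cuts on.

## The synthetic study and what it emulates

`synth_config()` defaults describe the emulated study conditions: 413
encounters over one calendar year with 65.9% day-shift arrivals; trauma
activation levels, demographics and injuries sampled with day/night
contrasts (older patients, more transfers and penetrating injuries at
night); an ED stay of 180–360 minutes followed by optional PICU (17%, 1–3
days) and floor (24–96 hours) phases recorded as a contiguous ADT timeline.
The observed cohort's hospital stays are often shorter than a day, but a
synthetic study needs each planted team to accumulate at least ~15 shared
night shifts in every sublog for its structure to be statistically
recoverable at all, so the inpatient phases are drawn at the long end of
the plausible range; this is a deliberate design condition of the study the
generator defines, stated here once.

Activity is emitted in bursts inside each (shift × location) window: 1–3
bursts, within-burst gaps uniform on 1–10 minutes, burst spacing uniform on
150–240 minutes. Keeping the within-burst support strictly below and the
between-burst support strictly above the 30–120 minute break grid makes the
planted burst structure exactly recoverable by segmentation — a property
the tests assert. Each window draws one planted community: during the day a
single merged community per location; at night five communities in the ED
and on the floor (ED core, neurosurgery, orthopaedics, otolaryngology or
paediatrics, plastic surgery or pain service) sharing the general
paediatric surgery attending and resident as hub roles, and a single
community in the PICU. Community members join a burst with probability 0.9;
hubs with probability 0.65, reflecting a coordinating service that rounds
with each specialty team intermittently — this keeps hub-edge weights
visibly below within-team weights, which is also what lets the weighted
similarity separate the five overlapping cliques, while still clearing the
15-shared-shift floor in the thinnest sublog (the ED at night, with only
~20–25 patient-shifts per community).

Spurious co-occurrence is modelled as near-one-off pairings: with
probability 0.3 per window, one pair of roles drawn (without replacement,
at most three draws per pair ever) from a roster-wide pool of non-hub
roles whose resolution survives a single out-of-context appearance; the
spurious burst is placed 125–150 minutes after the last planted burst,
just beyond the break grid's top, so it always forms its own segment yet
fits short ED windows. This
mirrors the abundant incidental co-occurrence of real logs — staff
documenting during transport through a foreign unit, one-off consults —
and produces the large low-count edge mass on which threshold sweeps
operate, while guaranteeing that no spurious pair accumulates more than 3
shared shifts. Records are independently reassigned to unresolvable actors
(0.2%, matching the scale of unresolvable-service exclusions such extracts
exhibit) or flagged student-/system-initiated (5%).

What the generator does **not** emulate: clinical text, medication codes or
injury epidemiology; heterogeneous documentation lag; seasonal or weekday
census variation; HCPs working across units as a norm rather than as
noise; and gradual team drift within a shift. Passing recovery tests
therefore demonstrate that the chain of methods is implemented correctly
and can recover structure of the planted kind at realistic scale — they do
not certify performance on real EHR extracts, where role resolution and
the elbow judgement are the fragile steps.

## Numerical and design choices

* Shift boundaries are half-open: day `[07:00, 19:00)`, night
  `[19:00, 07:00)`; minute-granularity "6:59" conventions are equivalent at
  this resolution.
* Gap comparison uses `>=` for breaks; ADT and location lookups use
  half-open intervals with clamping past the end.
* The Jenks boundary search is the two-class special case constrained to
  the grid; multi-class Jenks and change-point alternatives are out of
  scope.
* WPGMA merge heights are clamped to be non-decreasing to guard against
  floating-point inversions (WPGMA is monotone in exact arithmetic).
* All modal resolutions and clustering ties have explicit deterministic
  tie-breaks, and every stochastic step flows from the single configured
  seed, so identical configuration and seed reproduce byte-identical run
  directories (the provenance manifest records the seed and a config hash,
  and deliberately no timestamps).
* Whether the original workflow pooled gaps globally or per shift when
  optimising the break interval is not derivable from its description;
  both modes are provided and global pooling is the default, for
  comparability of the six networks.
* For notes, the creation timestamp is used as the event time; sign-off
  times are not modelled.

## Problem sizes used in validation

The bundled tests run the full pipeline at the default scale (413
encounters, ~100k activity records, about 1.5 minutes on one core) for the
end-to-end recovery checks, and small purpose-built fixtures (≤ 50 events,
≤ 8 edges) wherever an exhaustive oracle — brute-force GVF maximisation,
exhaustive co-occurrence enumeration, brute-force dendrogram-cut search —
provides the expected values.

## Known limitations

Role resolution replaces the chart reviews and directory lookups a real
deployment would use for unresolvable services with exclusion, and the
elbow criterion formalises a judgement that is ultimately visual — the
curve is always exported so that judgement can be revisited. Networks
aggregate an entire year; within-year drift is invisible. Communities are
edge partitions: a role pair interacting in two distinct team contexts
still contributes a single edge, assigned to one community.
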