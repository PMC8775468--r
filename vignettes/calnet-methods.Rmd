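---
title: "Reconstructing neuron-glial functional networks from calcium and MEA recordings"
author: "CalNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing neuron-glial functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CalNet)
```

## The problem

Dissociated hippocampal cultures form networks of neurons and
astrocytes whose collective state can be read out in two complementary
ways: calcium imaging, which reports slow (seconds-scale) fluctuations
of intracellular Ca^2+^ in every cell of a field of view, and
multi-electrode arrays (MEAs), which report fast extracellular action
potentials on a fixed grid of electrodes. CalNet implements the full
analysis chain for both readouts: per-cell calcium-event detection,
whole-field movie segmentation, reconstruction of a directed
*functional* network from lag-maximised cross-correlations, summary
statistics of that network, and network-burst analysis of MEA spike
trains. A synthetic-data generator with planted ground truth makes the
entire chain testable without any external recording.

The networks reconstructed here are functional, not anatomical: an
edge between two cells asserts only that their activity co-varies
strongly enough, possibly at a temporal offset, to exceed a fixed
correlation threshold.

## Calcium-event detection

The input is the per-cell fluorescence trace $F(t)$ (a
`TraceMatrix`, cells x frames, with a frame rate). A frame belongs to
an oscillation when

$$F(t) > \bar F + k \cdot \mathrm{dev}(F),$$

with $\bar F$ the global trace mean and $\mathrm{dev}$ the sample
standard deviation of the whole trace (`deviationMode = "sd"`;
`"sem"` is selectable, but note the standard error shrinks with
recording length, making detection depend on how long one records).
The threshold is one-sided because calcium transients are
positive-going. Maximal runs of supra-threshold frames form events
whose first and last frames give $T_{start}$ and $T_{end}$. Three
culture-level parameters summarise a recording
(`summarizeActivity()`): the share of working cells (cells with at
least one event), the oscillation frequency (events/min over active
cells) and the mean oscillation duration (s).

Two robustness guards shape the run decomposition:

* **Dip bridging** (`bridgeFrames`, default 2): a sub-threshold dip
  of at most two frames whose samples stay above half the threshold
  excess is bridged. On a cell whose trace spends a third of its time
  in transients, the global mean + SD threshold sits only ~2 noise SDs
  below the plateau of a 10x-amplitude transient, so without bridging
  roughly one in six events would be split in two by a single noisy
  frame. With the half-threshold gate, bridging changes detection on
  silent cells almost not at all.
* **Minimum duration** (`minDurationS`, default 4 s): runs shorter
  than this are dropped. The minimum is expressed in seconds, not
  frames, so detection does not change when the acquisition rate
  does. Four seconds is far below the ~12-s oscillations of mature
  hippocampal cultures but long enough that a silent cell produces a
  false event less than ~1% of the time in a 10-minute trace.

Because the bridging gate moves with the threshold, the textbook
monotonicity property ("raising the threshold never increases the
event count") is guaranteed only for the plain decomposition
(`bridgeFrames = 0`), and the test suite asserts it there.

The mean + SD threshold is *occupancy-dependent*: a cell firing
unusually often has a higher threshold relative to its plateaus, and
at occupancies above roughly 40% events may still fragment or shorten.
This is an intrinsic property of the thresholding rule, not of the
implementation; analyses of very high-rate cells should interpret
per-cell counts with that caveat.

## Whole-field movie segmentation

`findActivityEvents()` treats the image plane as a whole: a voxel
(frame, row, col) is active when its intensity exceeds its *pixel's*
temporal mean plus `pixelThresholdMultiplier` (default 2) temporal
SDs — per-pixel statistics, so uneven staining does not bias
detection. Active voxels are grouped into 26-connected spatio-temporal
components (diagonal connectivity in time tolerates one-frame
flicker); components smaller than `minVoxels` are discarded.

`splitEventByCells()` divides one event into cell regions: the event
is projected onto the image plane (maximum intensity per pixel over
the event's voxels), smoothed with a Gaussian of $\sigma = 2$ px to
suppress spurious maxima, and segmented by a watershed transform whose
merge tolerance defaults to 10% of the projection maximum. Every voxel
is assigned to the region of its pixel, so *the regions partition the
event* — this invariant, and the frame-wise conservation
$\sum_{cells} A = $ total active voxels, are asserted by the test
suite on randomly generated movies.

For each cell region, `extractCellSignals()` emits the two per-frame
characteristics used downstream: $C$, the mean intensity over the
region's pixels, and $A$, the number of the region's voxels active in
that frame (zero outside events). Regions are optionally linked to a
known cell map by nearest centroid within one cell radius (or one
pixel, for sub-pixel somata); headline network analyses use $C$, and
$A$ can be analysed identically.

Note the per-pixel mean + k SD rule needs the duty cycle of a pixel to
stay below roughly $1/(1 + k^2/(1+k^2))$; a pixel that is bright more
than ~20% of the time at $k = 2$ is classified as never active. This
mirrors the occupancy caveat above.

## Network inference

For every cell the characteristic is first detrended with a trailing
moving average of window $w$ frames (default: the frames spanning
10 s — longer than a transient's rise, shorter than slow drift):

$$\breve x_k = x_k - \langle x \rangle_{[k-w,\,k]},$$

with the window truncated at the recording start. For every unordered
pair $(i, j)$ the package computes the centred Pearson correlation
$\rho_{ij}$ at zero lag, and the lag-maximised correlation

$$\breve\rho_{ij} = \max_{-W \le \tau \le W} \rho_{ij}(\tau), \qquad
  \tau_{ij} = \arg\max_{-W \le \tau \le W} \rho_{ij}(\tau),$$

where $\rho_{ij}(\tau)$ is computed on the overlapping segments with
per-segment means (so $\rho_{ij}(0) = \rho_{ij}$) and $W$ defaults to
10 frames. Ties are broken towards the smallest $|\tau|$, positive
first; for generic signals the argmax is unique and swapping the pair
negates $\tau$. All lags are evaluated with one matrix cross-product
per lag, so the full pair table of a recording costs
$O(W n_{cells}^2 n_{frames})$.

`buildNetwork()` forms the graph: in undirected mode an edge requires
$\rho_{ij} > \rho_{thr}$ (default 0.3, the conventional significance
level for functional coupling in such cultures); in directed mode it
requires $\breve\rho_{ij} > \rho_{thr}$ and the sign of $\tau_{ij}$
orients the edge from the leading to the lagging cell. A directed edge
needs a nonzero lag; pairs whose optimum sits exactly at $\tau = 0$
are kept in the directed graph as undirected edges (set
`strictLag = TRUE` to drop them instead) — dropping them silently
would hide genuinely synchronous coupling. Zero-variance cells are
excluded from the vertex set before pairing, with a logged count.
Reported correlation levels use $\breve\rho$ (the lag-maximised
value), since functional similarity is defined here as the maximum of
the cross-correlation function over the allowed delays.

## Network statistics

`networkMetrics()` computes, for a reconstructed network over $n$
cells:

* $N_c$ — the number of functional connections ($|E|$);
* $N_n$ — the average number of connections per cell (equal to
  $2N_c/n$ for undirected graphs; asserted on every run);
* $S$ — the average signal-propagation speed,
  $\langle d_{ij}/|\tau_{ij}|\rangle$ over edges with nonzero lag,
  in um/frame and um/s ($d_{ij}$ is the distance between cell
  centroids). Zero-lag edges would divide by zero; they are excluded
  and counted (`nZeroLagExcluded`);
* $P$ — the mean $\breve\rho$ over *all* pairs;
* $P_a$ — the mean $\breve\rho$ over spatially *adjacent* pairs.
  Adjacency means somata in direct contact: centroid distance at most
  `contactSlack` (default 1.2) times the sum of the two radii; the 20%
  slack absorbs centroid and radius estimation error. $P_a$ averages
  over adjacent *pairs*, not adjacent edges, so sub-threshold
  neighbours count;
* the percentage of the maximum possible $n(n-1)/2$ connections
  ("all-to-all") that is realised.

## MEA network bursts

`detectBursts()` pools all spikes across electrodes in time order
(simultaneous spikes ordered by electrode id for determinism) and
partitions the pooled train into maximal runs in which every
consecutive inter-spike interval is at most `maxGapMs` (default
100 ms). A run that recruits at least `minElectrodes` distinct
electrodes (default 4, counted over the whole run) is a network
burst. Maximality guarantees bursts are non-overlapping, separated by
more than the gap, and own their spikes exclusively. The run-based
reading of the "interval" criterion is the standard network-burst
construction and makes the rule unambiguous. Note that growing the
gap can only merge runs, so the burst count is non-increasing in
`maxGapMs` whenever every run passes the electrode criterion (with
sparse background activity, merging can occasionally promote a
sub-criterion run above four electrodes).

`summarizeBursts()` normalises the burst count to a 10-minute record
(partial records are scaled; the scaling is recorded in provenance)
and reports mean spikes per burst and mean burst duration.
`activationPattern()` returns each electrode's first-spike delay from
burst start, in electrode-layout order, as the propagation fingerprint
of the burst.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the
conditions of a mature (21 DIV) hippocampal culture:

| parameter | default | rationale |
|---|---|---|
| `nCells` / `fieldSize` | 45 on 1000 x 1000 um | 4500 cells/cm^2 seeding density |
| `frameRate`, `nFrames` | 2 fps, 1200 frames | 10-min confocal time series |
| `transientDuration` | 12.37 s | measured oscillation duration in such cultures |
| `transientRate` | 1.34 events/min | measured oscillation frequency |
| `inactiveFraction` | 0.4 | ~59% of cells active |
| `transientAmplitude` / `noiseSd` | 10 / 1 | order-of-magnitude choices; no noise statistics are published for these recordings, so both are exposed in the config rather than calibrated |

Cells are placed by hard-disc rejection sampling (somata 5–10 um,
non-overlapping); event times are Poisson with a minimum separation so
that distinct transients never merge; the transient kernel is a brief
linear rise (5% of the duration), a plateau, and a sharp exponential
tail. The kernel shape was chosen so that the *nominal* duration and
the duration *measured* by mean + SD thresholding agree within a few
percent for thresholds anywhere between 10% and 70% of peak; a
20%-rise/exponential-decay kernel, by contrast, biases measured
durations ~40% low, which would make planted and detected durations
incomparable.

Coupling is planted as directed edges $(i \to j, \tau, p)$: each
spontaneous event of $i$ is copied into $j$, shifted by $\tau$ frames,
with probability $p$ (transmission failure) and amplitude
`couplingScale` (default 1: exact copies). Copies take precedence over
the target's own activity — a copy displaces any overlapping
spontaneous event of the target, and yields only to an earlier copy —
so per-cell ground-truth events are always disjoint and the event list
corresponds exactly to the painted transients. One root seed derives
independent per-stream seeds (placement, events, noise, spikes);
identical configurations are bit-identical.

`renderMovie()` paints each cell's disc at its current trace intensity
(overlaps add), giving fixtures for the segmentation stage;
`simulateSpikes()` plants network bursts (electrodes recruited in
sequence every `spacingMs`, bounded jitter validated against the gap
contract) over Poisson background.

**What the generator does not emulate:** photobleaching, motion,
focal drift, cell-type differences (neuron vs astrocyte kinetics),
bursty or rhythmic event timing, and amplitude variability across
events. Passing tests therefore demonstrate correctness of the
*algorithms* under controlled conditions, not performance on any
particular microscope's data.

## The edge-recovery benchmark

`recoveryBenchmarkConfig()` freezes one scenario for scoring directed
edge recovery: 30 cells of which 10 are autonomously active hubs and
20 are passive followers, 40 feed-forward edges (out-degree <= 4,
in-degree <= 2, lags 2–8 frames), transmission probability 0.6,
6-s transients at 1.34 events/min, a 60-minute recording at 2 fps,
and noise at one fifth of the transient amplitude (SNR 5). Recovery is
scored against the planted truth as the F1 of undirected pair
detection plus, separately, the fraction of recovered edges whose
orientation matches the planted lag sign.

Each choice addresses a specific identifiability limit of
marginal-correlation inference:

* **Feed-forward topology.** Correlation cannot separate a direct
  link from coupling induced by a cascade (that would require partial
  correlation, which is out of scope), so the benchmark truth
  contains no source-that-is-also-target.
* **Passive followers.** With 40 edges over 30 cells, at least ten
  targets receive two inputs. If every cell also fired autonomously,
  each edge's share of its target's variance falls far enough that
  its correlation drops below the 0.3 threshold — no faithful additive
  generator can reach high recall in that regime. Followers without
  pacemaker activity are also the biologically natural picture of
  driven cells.
* **Transmission probability 0.6.** Independent transmission failures
  decorrelate the two targets of a common source (their shared events
  are the $p^2$ fraction copied to both) while each true edge keeps a
  $p$ fraction: with $p = 0.6$, true pairs sit near
  $\breve\rho \approx 0.4$ and confounded pairs near $0.2$, bracketing
  the fixed 0.3 threshold.
* **60-minute recording.** The sampling error of $\breve\rho$ at
  10 minutes (~0.1) blurs that separation; an hour-long recording —
  routine for slow calcium dynamics — resolves it.

At the frozen settings the benchmark yields mean F1 ≈ 0.92 and
lag-sign accuracy 1.0 over ten seeds.

## Numerical and interface choices

* Correlations are computed with per-lag matrix cross-products;
  results agree with naive loop implementations to 1e-10 (asserted on
  random pairs).
* Traces, cell maps and spikes are CSV at full precision (17
  significant digits), making write-then-read bitwise exact. Movies
  are multi-page grayscale TIFF with 32-bit samples scaled by a
  power-of-two dynamic range; the writer quantises to
  $\mathrm{range}/(2^{32}-1)$ (~1.5e-8 intensity units), far below
  any noise floor. Networks are GraphML with vertex coordinates and
  edge weight/lag/direction attributes.
* `runPipeline()` sequences simulate -> detect-events -> (segment) ->
  infer-network -> metrics -> bursts from one validated configuration
  (unknown keys rejected; missing `frameRate` named in the error).
  Identical configurations give byte-identical analysis artifacts; the
  provenance record carries the only timestamp.
* Test and benchmark problem sizes (tens of cells, 10–60-minute
  simulated recordings, 40 x 40 px movies) were chosen as the smallest
  sizes at which every statistical check is comfortably resolved.

## A worked example

```{r example, eval = FALSE}
library(CalNet)

bench <- recoveryBenchmarkConfig(seed = 1)
sim <- simulateTraces(bench$config)

events <- detectEvents(sim$traces)
summarizeActivity(events, nCells = 30, durationMin = 60)

pairs <- pairwiseCorrelations(sim$traces, W = 10)
net <- buildNetwork(pairs, cellMap = sim$groundTruth$cellMap,
                    rhoThreshold = 0.3, mode = "directed",
                    frameRate = 2)
net
edgeRecoveryStats(net, sim$groundTruth$plantedNetwork)
networkMetrics(net, pairs, sim$groundTruth$cellMap)
```

## Known limitations

* Marginal correlation admits confounded (common-source) pairs as
  edges whenever their shared variance exceeds the threshold; the
  benchmark quantifies this, it does not remove it.
* The global mean + SD event threshold degrades at per-cell
  occupancies above ~40% (splits) and the per-pixel variant above
  ~20% duty (missed pixels).
* Directionality from lag signs assumes the optimal lag reflects
  propagation; synchronous coupling (lag 0) is left unoriented.
* The MEA module ingests spike tables (CSV); spike detection from raw
  voltage and vendor file formats are out of scope.
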