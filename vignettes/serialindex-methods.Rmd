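---
title: "Still-image serial crystallography processing with serialindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Still-image serial crystallography processing with serialindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialindex)
```

## The problem

A serial crystallography experiment collects many thousands of still
diffraction snapshots, each from a single micro-crystal in a random, unknown
orientation. Per frame, the processing pipeline must detect Bragg peaks,
decide whether the frame contains a usable pattern (a *hit*), determine the
crystal orientation and unit cell from the peak positions (*indexing*),
predict where all reflections fall, and measure their intensities. For
real-time operation the whole chain must run in a fraction of a second per
frame, which shapes every algorithmic choice in this package: precomputation
of everything that does not change between frames, subsampled statistics,
and an indexing algorithm built around the FFT.

`serialindex` implements this chain end to end for a single-panel detector,
together with a seeded synthetic-pattern simulator, so that every stage can
be exercised and verified without any experimental data.

## Geometry and conventions

One fixed laboratory frame is used throughout: the beam travels along +z,
the detector plane sits at z = camera length, the fast scan axis maps to +x
and the slow scan axis to +y. Pixel indices are 0-based and a pixel's
laboratory position is its centre; membership of a pixel in a
laboratory-frame mask rectangle is decided by its centre. Internal units
are Angstrom (wavelength), inverse Angstrom (reciprocal space) and
millimetre (laboratory coordinates).

A peak at laboratory position p with unit direction s = p/|p| maps to
reciprocal space as q = (s - z)/lambda. This Ewald construction is
monochromatic: every mapped point satisfies |q + z/lambda| = 1/lambda
exactly, which the test-suite asserts as an invariant.

Laboratory-frame mask rectangles (e.g. a beam-stop shadow) are converted
once per geometry into pixel-index ranges, so per-frame masking reduces to
rectangle fills plus the sentinel-value test (pixels whose readout equals
65535 are bad). Image binning (factors 2-4) sums unmasked member pixels in
square blocks and marks an output pixel bad if any member is bad; for the
full 4148 x 4362 detector format, factor 2 yields 2074 x 2181.

## Peak search with annular background statistics

The background under a still pattern varies strongly with radius and only
weakly with azimuth, so the search thresholds pixels against per-annulus
statistics. The annulus assignment (1-pixel-wide rings,
`floor(radius)`) depends only on the geometry and mask and is computed
once per run, not per frame.

Per frame, annulus means and standard deviations are estimated robustly:
three iterations discard pixels above mean + 3 sd before the final
estimate, because the Bragg peaks themselves would otherwise bias the
background. In fast mode only a fixed random subsample of at most 100
pixels per annulus enters the statistics; the sample positions are drawn
once per annulus map from a stored seed, so they are identical for every
frame of a run, and for annuli no larger than the sample the fast result
equals the full one exactly.

Candidate pixels exceed `max(adc_threshold, mean + min_snr * sd)`; they are
grouped by 8-connectivity, size-filtered (2-200 pixels), and summarised by
the background-subtracted intensity-weighted centroid. The reported
signal-to-noise ratio is `intensity / (sd_annulus * sqrt(n_pixels))`, with
the annulus taken at the centroid. Defaults (`min_snr` 6, `adc_threshold`
10 counts, 2-200 pixels) are conventional starting points and fully
configurable; the experiments this mirrors did not publish their values.

## The autoindexing algorithm

Indexing recovers direct-space lattice vectors as strong one-dimensional
periodicities of the reciprocal-space peak positions:

1. Map the peaks to reciprocal space (above).
2. Order the points by descending intensity and keep at most `max_points`
   (2000; 120 in fast mode). Form triplets: all of them if there are no
   more than `max_triplets` (20 000; 10 000 in fast mode), otherwise that
   many distinct seeded-random triplets. "First points" is interpreted as
   strongest-first, since peak lists carry no other canonical order.
3. For each (non-collinear) triplet: take the unit normal of its plane,
   project *all* considered points onto it, histogram the signed distances
   into 1024 bins spanning their range R (first bin = most negative, last
   bin = most positive, half-open bins with the maximum closed), and
   Fourier-transform the histogram. Transform index k corresponds to the
   direct-space length L = k/R; the index with the largest magnitude
   inside the search band wins. The band (2 Angstrom to 1.2 x the longest
   reference axis; 250 Angstrom without a reference) also serves to
   suppress the low-frequency end, with the DC term always excluded — the
   index-to-length convention and the low-frequency handling are the two
   points the algorithm's verbal description leaves open, and both are
   explicit options here.
4. Refine the repeat by iterated closed-form least squares: assign
   m_i = round(d_i / p), fit p = sum(m_i d_i)/sum(m_i^2) over points
   within `fit_tolerance` (0.15) of an integer multiple (m = 0 points are
   excluded: the origin slab carries no period information), and repeat
   until the assignment is stable. Accept the candidate only if more than
   six points fit. The accepted vector is then refined in 3D by least
   squares over sum |q_i . t - m_i|^2 (m = 0 points are included here,
   because they do constrain the direction), which removes the small tilt
   inherited from a single triplet normal.
5. Merge duplicates (equal up to sign, lengths within 1%, directions
   within 3 degrees), keeping the best fit count and summing the triplet
   votes.
6. Assemble the basis from the three shortest independent candidates
   (|scalar triple product| of unit vectors > 0.05), requiring the volume
   to match the reference within `volume_tolerance` (0.10) when a
   reference is given, trying further combinations in order of increasing
   total length up to `combination_budget` (100), and restoring
   right-handedness.

### Robustness additions

At desk scale the bare recipe drowns: a 56-peak pattern yields roughly
12 000 raw candidates, most of them chance periodicities fitting a dozen
points, while the true axes fit essentially every reflection. Three
voting-and-validation steps — in the spirit of the original
one-dimensional-search indexers — make the assembly reliable, and all of
them are exposed in `asdf_options()`:

* only candidates with at least `min_fit_fraction` (0.75) of the best
  candidate's fit count enter merging (with a `max_candidates` cap);
* among near-parallel candidates (3 degrees) the one with the most fitting
  points, then the most triplet votes, is kept, so a slightly mis-refined
  repeat cannot shadow the well-supported one;
* an assembled basis must index at least `min_indexed_fraction` (0.8) of
  the points to within `hkl_tolerance` (0.2) of integer Miller triples,
  and among acceptable combinations the one indexing the most points at
  half that tolerance wins (ties go to the shortest basis). A correct cell
  indexes nearly all peaks; a chance basis almost none, which also keeps
  the false-positive rate on lattice-free point sets at the per-cent
  level.

Each indexing call draws its randomness from one seed derived from the
global seed and the frame id, so results are bit-reproducible and
independent of processing order. Retrying with peak deletion (up to five
retries, two weakest peaks removed each time) is available in the pipeline
but off by default, matching a real-time configuration that does not
retry failed attempts.

## Cell checking

An indexing solution may be any primitive representation of the lattice,
so candidate and reference are compared after Niggli reduction
(Krivy-Gruber conditional algorithm on the metric parameters, relative
tolerance 1e-5, with the accumulated unimodular transform applied to the
basis). Cells match when every reduced axis agrees within `tol_length`
(5% relative) and every reduced angle within `tol_angle` (1.5 degrees);
the G6 vectors (a^2, b^2, c^2, 2bc cos alpha, 2ca cos beta, 2ab cos gamma)
of both reduced cells are reported for diagnostics. Parameter-wise
tolerances were preferred over a G6 metric radius as simpler to calibrate;
the G6 representation is retained in the report.

## Counting unique reflections

`count_unique_reflections()` enumerates Miller indices in a resolution
window, merges them into Laue-class representatives (Friedel mates always
merged; the representative is the lexicographically greatest equivalent
tuple) and counts classes. Systematic absences are included — merging by
Laue symmetry cannot know the space group — and both resolution bounds are
inclusive with a 1e-9 relative guard so classes sitting exactly on a bound
are not lost to floating-point rounding: for the tetragonal
79.2 x 79.2 x 38 cell the (44,0,0) class has d = 79.2/44 = 1.80 exactly,
yet naive double arithmetic places it at 1.7999999999999998. With the
low-resolution end open (d_max = Inf) and d_min = 1.80 this count is
11 716 for Laue group 4/mmm; a hard cutoff at the rounded printed value
56.00 would wrongly drop the (1,0,0) and (1,1,0) classes (d = 79.2 and
56.0028) that belong to the full low-resolution range.

## Prediction and integration

Prediction enumerates reciprocal-lattice points of the oriented cell and
keeps those whose excitation error e = |q + z/lambda| - 1/lambda lies
within `e_max_abs + e_max_rel * |q|` — a linear-in-|q| band, the minimal
still-diffraction convention in the absence of a physical partiality
model (partiality modelling is out of scope). Integration sums
background-subtracted counts over a disc (radius 4 px) around the
predicted position, with the background taken as the median of a 5-7 px
annulus (median rather than mean: robust to neighbouring spots), and
sigma = sqrt(sum counts + n_px * background variance). Discs touching bad
pixels are flagged `masked`, discs crossing the detector edge
`off-detector`.

The simulator uses the same enumeration with the same tolerance
parameters, which makes simulation and prediction exact duals: on a
noise-free pattern the simulated and predicted hkl sets are equal, a
property the tests assert.

## The simulator as the package's test bed

`simulate_peaks()` draws a Haar-uniform orientation (quaternion method),
enumerates the reflections excited at that orientation, projects them to
the detector and then degrades the list (positional jitter, dropped peaks,
spurious peaks, exponential intensities). `render_frame()` turns a peak
list into an integer image: Poisson background plus 2D Gaussian spots,
sentinel values stamped into masked regions. `make_run()` produces seeded
multi-frame runs with a chosen hit fraction and a ground-truth manifest.

The study conditions for the recovery experiments are fixed in the test
helpers: a 512 x 512-pixel detector, 0.2 mm pixels, 100 mm camera length,
1.0 Angstrom wavelength, and the 79.2 x 79.2 x 38 Angstrom tetragonal
reference cell; an excitation tolerance of 1e-4 + 1e-4 |q| puts typical
patterns in the 25-60-peak range at this geometry. These were chosen once
as a desk-scale analogue of a small-protein still experiment.

What the simulator does *not* emulate — detector point spread beyond a
Gaussian, structure-factor physics, polarization, partiality, correlated
background — bounds what passing tests show: they validate the geometry,
search, indexing and bookkeeping chain, not photometric accuracy on real
detectors.

## Profiling and the pipeline

The profiler records one wall-clock tree per processing-loop iteration
(wall clock, not CPU time, so waiting on a data source is visible), with
a record emitted even when processing breaks off early. Aggregation
flattens segments by name; each name receives its self-time (duration
minus instrumented children), so the per-record category times sum to the
root duration identically. Records are averaged in consecutive batches in
completion order (final partial batch kept), the ten largest categories
by whole-input total are reported and the rest pooled as `other` —
whole-input ranking keeps the category set stable across batches.

The in-memory `run_stream()` reproduces the consumer-group contract of a
streaming data service: within a group each message is delivered exactly
once, distinct groups each see the whole stream in order, and an empty
stream yields a distinguishable timeout signal (default 3 s). The
pipeline partitions frames across logical workers round-robin and merges
output by frame id, so every scientific output is invariant to the worker
count; working buffers (static mask, annulus map) are allocated once per
run and reused across frames. Batched frame storage writes RDS batch
files (1000 frames each by default) plus a JSON master index that exposes
a run as one logical stack with `floor(k/batch)` / `k mod batch`
addressing and bit-identical round trips.

## Numerical choices and degenerate inputs

* Histogram bins are half-open with the maximum clamped into the last
  bin; all-identical distances are an error (no periodicity exists).
* The FFT argmax takes the first maximum on exact ties.
* Niggli reduction uses relative tolerance 1e-5 and caps at 1000 steps;
  coplanar bases are rejected at cell construction.
* Indexing failures (too few peaks, no candidates, no acceptable basis)
  are result objects with a reason, never exceptions; errors are reserved
  for malformed inputs.
* All randomness (triplet sampling, subsample positions, simulation)
  flows through named seeds; per-frame seeds derive from
  (global seed, frame id).

## Problem sizes

The shipped test-suite sizes were chosen to exercise the contracts at
desk scale: 200 noise-free patterns for the recovery and fast-mode
comparisons, 50 rendered frames for the peak-search comparison, a
200-frame mixed run for pipeline determinism, 1000 random unimodular
transforms for the reduction invariance, and a single full-format
4148 x 4362 binning check.

## Known limitations

Single-panel detectors only (the geometry object carries a panel list to
leave room for extension); no multi-lattice indexing; no cell refinement
beyond the least-squares fits described above; two Laue groups (-1 and
4/mmm) for reflection counting; the stream layer is an in-process
analogue, not a network service.
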