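---
title: "Methods: audification of NMR FIDs and the ZPFD anti-aliasing procedure"
author: "nmraudify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: audification of NMR FIDs and ZPFD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmraudify)
```

## The signal model

Every operation in this package works on one model of the NMR signal: the
free-induction decay is a superposition of exponentially decaying complex
sinusoids sampled every dwell time $\Delta t = 1/\mathrm{SW}$,

$$ d_k \;=\; \sum_{j=0}^{L-1} A_j e^{i\Phi_j}\, e^{-k\Delta t/\tau_j}\,
   e^{2\pi i\, k\Delta t\, w_j} \;+\; \varepsilon_k, \qquad k = 0,\dots,N-1, $$

where $A_j$, $\Phi_j$, $w_j$ and $\tau_j$ are the amplitude, phase,
display frequency and transverse decay time ($T_2$) of resonance $j$, and
$\varepsilon_k$ is optional complex white Gaussian noise. Pure exponential
decay is exactly the assumption of Lorentzian lines: the absorption-mode
linewidth is $1/(\pi\tau)$ full width at half maximum. No spin physics is
simulated — multiplets exist only as lists of Lorentzian peaks, without
coupling evolution.

### Frequency-axis convention

The canonical internal axis is the *display* axis: frequencies in
$[0, \mathrm{SW})$, 0 Hz at the rightmost (most shielded) point of the
plotted spectrum, increasing leftward, in steps of $\mathrm{SW}/N$, bin
$m$ at $m\cdot\mathrm{SW}/N$ (0-based). The plotting convention of
carrier-centered spectra rotates the DFT output by $N/2$ bins to cover
$-1/(2\Delta t)$ to $(N/2-1)/(N\Delta t)$; re-expressing that
carrier-centered view back on the display axis undoes the rotation, so
`fourierTransform` stores the unrotated DFT in natural bin order. This is
the only axis on which the folding arithmetic below takes its simple form.
Chemical-shift input (ppm) is converted at the boundary by
$\mathrm{ppm} \times$ observe frequency (MHz); downfield-left ordering is
a display concern only.

### Transform normalization

The forward DFT is unnormalized and the inverse carries $1/N$ (the common
signal-processing pair). This must be fixed because the amplitude scale of
the ZPFD output depends on it: with this pair, a unit-amplitude resonance
produces an augmented FID of amplitude $1/2$ before normalization, which
the final headroom normalization makes irrelevant.

## Aliasing and the ZPFD procedure

Playing the real channel of a quadrature FID as audio at rate
$\mathrm{SW}$ discards the imaginary part; a real signal cannot
distinguish $+f$ from $-f$, so every resonance above the Nyquist frequency
$\mathrm{SW}/2$ is reflected: it is heard at
$\mathrm{alias}(f) = \mathrm{SW} - f$. `realAudify` implements this path
deliberately, as the demonstration of the artefact.

`zpfdAudify` removes it. Given the $N$-point complex spectrum, an
$2N$-point frequency vector is built whose first $N$ bins (display
frequencies $[0, \mathrm{SW})$ at resolution $\mathrm{SW}/N$) hold the
spectrum and whose remaining $N$ bins are zero; the inverse DFT of this
vector is the augmented FID, and its real part is played at
$2\cdot\mathrm{SW}$. Two things follow by construction:

* every resonance sits below the new Nyquist frequency $\mathrm{SW}$, so
  the real part alone represents it at its true display frequency — no
  folding for any $f \in [0, \mathrm{SW})$;
* the duration is unchanged: $2N$ samples at $2\cdot\mathrm{SW}$ last
  exactly $N\Delta t$, the acquisition time, so pitch fidelity does not
  alter playback length.

The operative contract is that the spectrum occupies the positive-frequency
half of the inverse-DFT input and the other half is zero; zeroing the
negative-frequency half is what transfers the information of the imaginary
channel into the real part (the augmented FID is an analytic-signal
construction). An equivalent variant pads $N/2$ zeros on both sides and
then shifts the carrier; the one-sided form is used because it needs no
extra shift.

Reference-offset correction is applied in the time domain before the
transform: multiplying the FID by $e^{-i 2\pi \Delta f\, k\Delta t}$
shifts every display frequency by $-\Delta f$ (mod SW), so the pitches
heard match the referenced axis (TMS at 0). The CLI exposes it as
`--offset`; it defaults to 0 because whether a given data set is already
referenced is not knowable from the FID alone.

## Audio rendering choices

* **Sample rates** are rounded to integer Hz for WAV compatibility; the
  worst-case pitch error is below 0.5 Hz over kHz-scale widths.
* **No resampling to 44.1 kHz.** Pitch fidelity to the spectrum is the
  point; playback-device compatibility is left to players.
* **Normalization** scales to a peak amplitude of 0.9 (headroom before
  16-bit quantization); silence passes through. WAV output is mono 16-bit
  little-endian PCM in the canonical 44-byte layout, written and read by
  the package itself so the byte layout is fully specified and the
  round-trip error is bounded by one quantization step (1/32768).
* **The analyzer** (`analyzeAudio`) computes the DFT magnitude of the real
  audio over $[0, \mathrm{rate}/2]$, reports local maxima above a
  threshold (default 0.05 of the global maximum), and merges maxima closer
  than one resolution bin. No window function is applied: decaying FIDs
  are self-windowed, and windowing would broaden the very lines whose
  positions the analyzer is meant to verify.

## Peak picking

`pickPeaks` stands in for full spectral deconvolution with a deliberately
simple two-stage picker:

1. the noise floor $\sigma$ is the scaled median absolute deviation of the
   magnitude spectrum (peaks are sparse, so the median sits on peak-free
   context); local maxima above $k\sigma$ (default $k = 5$) are candidate
   peaks. Maxima are located *circularly*: the DFT is circulant, so a line
   near one band edge continues across the other, and non-circular
   detection would manufacture a phantom edge peak.
2. each candidate is refined by least squares over a window of $\pm 5$
   bins (wrapped at the edges, in an unwrapped local frequency
   coordinate), fitting the magnitude profile of a complex Lorentzian,
   $|A/(1/\tau + 2\pi i (f - w))|/\Delta t$. This yields a sub-bin
   frequency, an amplitude on the synthesis scale and $\tau$. Phases are
   fixed at zero. Non-convergence falls back to the grid maximum plus its
   half-height width (the magnitude profile has full width
   $\sqrt{3}/(\pi\tau)$ at half height), with a message.

The magnitude profile is used, rather than the absorption (real) part,
because it is insensitive to phase; its shape differs from the absorption
Lorentzian (square-root form, wider at half height), which the fit model
accounts for. The continuous-FT approximation to the finite DFT sum biases
$A$ and $\tau$ by of order $\Delta t/\tau$ and by truncation
($e^{-T_\mathrm{acq}/\tau}$); at the fixture scale (N = 4096,
$T_\mathrm{acq} \approx 8\tau$) both are far inside the 10 % recovery
tolerance the tests assert.

## Region-wise audification

Excising spectral regions and inverse-transforming them directly produces
edge discontinuities and ringing, and bandpass filtering brings filter
design and phase distortion with it; the package therefore implements
only the resynthesis route. For each region of interest, taken in
ascending display frequency (right to left on the plotted spectrum, high
field first): the picked peaks inside the region are re-synthesized as a
sub-FID with phases zero and no noise (`synthSubfid`), transformed, and
rendered through ZPFD. Frequencies stay on the absolute display axis — a
region keeps its spectral pitch rather than being transposed into a common
band, so position in the spectrum maps to pitch in the audio.

Segments are assembled as follows, with the unspecified constants fixed as
package defaults and exposed as CLI options:

* **segment duration**: one shared duration, min(acquisition time,
  5 × the largest picked $\tau$), so late segments are not dominated by
  silence after the signal has decayed (at $5\tau$ the envelope is below
  0.7 % of its start). A single shared duration (rather than a per-region
  one) keeps segment boundaries arithmetically predictable —
  total length = segments + gaps exactly;
* **gap**: 0.2 s of silence between segments;
* **taper**: a 10 ms raised-cosine ramp at both ends of each segment,
  against clicks at the splice points;
* a region with no picked peaks contributes a *silent segment of the same
  duration*, so the positional meaning of the sequence is preserved;
* one single normalization pass over the concatenated result, so relative
  intensities between regions survive (per-segment normalization would
  equalize loud and weak regions).

## The synthetic generator as test bed

All test inputs are generated by `synthFid` and the two fixtures. The
four-peak fixture is the worked aliasing example: SW = 1000 Hz and four
equal-amplitude resonances at 100, 300, 650, 750 Hz are its defining
parameters; the remaining choices (N = 4096, $A_j = 1$, $\Phi_j = 0$,
$\tau = 0.5$ s, no noise) are package choices made because the quantities
of interest — peak locations — are invariant to them, and narrow lines
(0.64 Hz against a 0.244 Hz grid) make detection unambiguous. The
three-region fixture places synthetic clusters at 1.6/1.7/2.4 ppm
(aliphatic), 5.4/5.5 ppm (olefinic) and 7.2/7.3/7.4 ppm (aromatic) on a
100 MHz, 0–10 ppm axis with $\tau = 0.4$ s: plausible positions for a
molecule bearing all three proton classes, explicitly labelled synthetic
and not modelled on any real compound's shifts or couplings. The noise
model is independent complex Gaussian per point, seeded.

What passing tests therefore show: the frequency bookkeeping
(folding law, anti-aliasing, offset shifts, region fidelity) and parameter
recovery are correct for sums of well-separated Lorentzians. What they do
not show: behaviour on real data with baseline distortion, phase errors,
non-Lorentzian lineshapes, strong coupling, solvent signals or heavily
overlapped multiplets — the picker in particular assumes resolvable local
maxima. Problem sizes in the suite (N from 8 to 16384, up to 10 random
peaks, 50-trial property runs) were chosen as the smallest that exercise
each contract at its stated tolerance.

## Numerical and degenerate-case decisions

* N is kept a power of two through `zeroFill`; the transform itself
  accepts any length (the half-length rotation argument would use
  $\lfloor N/2 \rfloor$, but that path is defensive only).
* First-point scaling (halving $d_0$ before transformation, applied by
  some processing chains) is *not* applied; importers of vendor data
  should know their chain's convention.
* No phase correction, baseline correction or solvent suppression:
  synthesis phases are zero throughout this pipeline.
* All-zero inputs: silent FID transforms to a silent spectrum, silent
  audio normalizes to itself and analyzes to an empty peak list; an empty
  spectrum or empty audio is an error.
* The JSON FID interchange writes 17 significant digits, the minimum that
  round-trips IEEE doubles exactly; a stored dwell time inconsistent with
  $1/\mathrm{SW}$ beyond $10^{-6}$ relative is recomputed from SW with a
  warning (quadrature convention wins).
* Determinism: every source of randomness is seeded through the API; a
  seeded simulation, the WAV bytes it produces and the CLI outputs are
  bit-reproducible across runs.

## Known limitations

1D spectra only; mono audio only (no stereo encoding of the quadrature
pair); no vendor-format readers (the JSON interchange is the single ingest
point an adapter would target); region selection is user-supplied, with no
automatic multiplet analysis; and the picker's simple local-maximum stage
will merge peaks closer than the analysis resolution.
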