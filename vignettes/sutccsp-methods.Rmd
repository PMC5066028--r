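---
title: "Complex common spatial patterns for motor-imagery EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex common spatial patterns for motor-imagery EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sutccsp)
```

# The problem

Two-class motor-imagery brain-computer interfaces discriminate imagined
left- from right-hand movement using the sensorimotor mu (8–13 Hz) and
beta (13–25 Hz) rhythms, whose power desynchronizes contralaterally to the
imagined hand (ERD). The classical feature extractor is common spatial
patterns (CSP): spatial filters that jointly diagonalize the two classes'
covariance matrices, maximizing the variance ratio between classes.

Plain CSP applied to the summed rhythms sees only *total* band power. If
the two rhythms are represented as one complex signal,

$$ z(t) = z_\mu(t) + j\, z_\beta(t), $$

the covariance $C = E[zz^H]$ carries the mu+beta power **sum**, while the
pseudocovariance $P = E[zz^T]$ carries the mu−beta power **difference**
and the mu/beta cross-correlation. For circular signals (equal band
powers, no cross-correlation) $P = 0$; motor-imagery rhythms are
noncircular, and the power-difference channel turns out to carry
class-discriminative information that the covariance hides. This package
implements the spatial-filter family that exploits it:

* **CSP** — real filters on the summed rhythm $z_\mu + z_\beta$;
* **CCSP** — complex filters using $C$ only;
* **SUTCCSP** — complex filters diagonalizing $C$ *and* $P$
  simultaneously through the strong uncorrelating transform (SUT).

# The SUTCCSP construction

With class covariances $C_L, C_R$ and pseudocovariances $P_L, P_R$
(per-trial sample statistics of zero-mean data, trace-normalized by each
trial's covariance trace, then class-averaged), the composites are
$C_c = C_L + C_R$ and $P_c = P_L + P_R$. The pipeline is:

1. **Whitening.** $C_c = U_c \Lambda_c U_c^H$,
   $G = \Lambda_c^{-1/2} U_c^H$, so $G C_c G^H = I$ on the retained
   subspace (eigenvalues below `rank_tol` of the maximum are dropped).
2. **Takagi factorization.** The whitened composite pseudocovariance
   $\bar P_c = G P_c G^T$ is complex symmetric and factors as
   $\bar P_c = Y \Lambda Y^T$ with $Y$ unitary and $\Lambda$ real,
   nonnegative, descending.
3. **SUT.** $Q = Y^H G$ satisfies $Q C_c Q^H = I$ and
   $Q P_c Q^T = \Lambda$; the pseudocovariance analogue is
   $\hat Q = \Lambda^{-1/2} Y^H G$ with $\hat Q P_c \hat Q^T = I$.
4. **Joint diagonalization.** $S_L = Q C_L Q^H$ is Hermitian; its
   eigensystem $B$ gives covariance filters $W = B^{-1} Q$ with class
   eigenvalues $\Lambda_L + \Lambda_R = I$. Likewise
   $\hat S_L = \hat Q P_L \hat Q^T$ (complex symmetric) gives
   pseudocovariance filters $\hat W = \hat B^{-1} \hat Q$.
5. **Features.** Per trial, $V = W A$ and $\hat V = \hat W A$; the
   first/last `m_pairs` components of each contribute power features.

Two constructions deserve comment because the source material leaves them
open:

* **The $\hat G$ question.** The printed filter definitions are
  $W = B^{-1}G$, $\hat W = \hat B^{-1}\hat G$ with $\hat G$ undefined. We
  implement $W = B^{-1}Q$ and $\hat W = \hat B^{-1}\hat Q$ — the only
  reading under which every printed identity and the variance-ratio
  property hold. For CSP/CCSP the Takagi step is absent and $Q$ reduces
  to $G$, and the SUTCCSP covariance filters provably coincide with
  CCSP's (a regression test asserts this), so the choice affects no
  baseline.
* **The pseudocovariance eigensystem.** $\hat S_L$ is complex symmetric,
  not Hermitian. Its eigenvectors are normalized *complex-orthogonal*
  ($v^Tv = 1$), which makes $\hat B^{-1} = \hat B^T$: the similarity
  diagonalization and the congruence by $\hat B^T$ coincide, the identity
  $\hat\Lambda_L + \hat\Lambda_R = I$ holds exactly, and the filtered
  pseudo-powers realize the eigenvalues. Eigenvalues are reported as real
  parts; on all fixtures the imaginary parts are numerical noise.

**Features in detail.** Covariance components contribute
$\log(\mathrm{var}(v)/\sum\mathrm{var})$ (scale-invariant log power).
Pseudocovariance components contribute the circularity-normalized
pseudo-power $\mathrm{Re}(\overline{\hat v^2})/\overline{|\hat v|^2} \in
[-1,1]$ — the per-component mu/beta power-difference ratio, which is the
quantity $\hat W$ separates and is scale-invariant by construction. The
`raw` transform gives unnormalized powers for both blocks.

# Rhythm extraction with noise-assisted MEMD

Multivariate empirical mode decomposition projects the multichannel
signal onto `n_directions` unit vectors (a low-discrepancy Hammersley set
mapped to the hypersphere), interpolates channel-space envelopes through
each projection's extrema (natural cubic splines, mirror extension of two
extrema per boundary), and sifts against the direction-averaged mean
envelope until a Rilling-style criterion fires
($\theta_1 = 0.05$, $\theta_2 = 0.5$, $\alpha = 0.05$, hard cap 100
iterations). All channels share one aligned mode set, and modes plus
residue reconstruct the input to machine precision — both properties are
tested, not assumed. Noise assistance appends one white-noise channel
(default SD 2% of the mean channel SD) before sifting and discards its
modes afterwards.

The stopping thresholds, direction count (default 64) and noise variance
are conventions from published MEMD practice, not values fixed by the
source study, and are exposed in `sift_config()`. Mode-to-rhythm
assignment offers the canonical `fixed` policy for 160 Hz motor-imagery
recordings (mode 4 → mu, modes 2+3 → beta) and an `auto` policy that
averages Bartlett periodograms over the population and assigns each mode
to the band (mu, beta, or neither) holding the largest power fraction.
The Bartlett periodogram uses window and FFT length 640 by default and is
normalized so that the spectral sum equals the windowed-signal variance.

# The synthetic world

`generate_dataset()` emulates exactly the structure the downstream
analysis claims to exploit, with everything else intentionally plain:

* two spatial sources (left and right sensorimotor patches), each
  emitting an independent band-limited Gaussian mu and beta signal per
  trial (band-pass filtered white noise; pure tones would make sifting
  untestably clean);
* a montage-driven mixing matrix (ipsilateral 1, contralateral 0.15,
  midline $\sqrt{0.5}$ per hemisphere so midline power is the hemisphere
  average). One column per *patch*, shared by both rhythms, as for a
  cortical generator producing both — this is also what makes the
  difference-only construction exactly covariance-invariant;
* class- and hemisphere-dependent RMS amplitudes with multiplicative
  log-normal per-trial jitter (sdlog 0.1) so covariance estimates have
  realistic variability — a stand-in, not a claim about any real
  recording's inter-trial statistics;
* additive broadband sensor noise (default SD 0.5 against unit-RMS
  sources);
* defaults 160 Hz, 640-sample (4 s) trials, 14 channels.

The **difference-only** configuration swaps each band's hemisphere
amplitude pair between classes, with mu pair $(m_1, m_2)$ and beta pair
$(b_1, b_2)$ tied by $m_1^2 - m_2^2 = b_2^2 - b_1^2$. Summed band power
is then identical across classes at every channel (checked analytically
and empirically), so CSP and CCSP are structurally blind, while the
mu−beta difference remains class-lateralized for SUTCCSP. The pairs are
chosen mu-dominant ($m_i > b_i$) so the power difference is positive on
both hemispheres: a literal single-pair swap would make it antisymmetric
across hemispheres and put a zero in the asymmetry-index denominator,
leaving the central-pair sign analysis undefined.

What a green test does **not** establish: the generator has no
volume-conduction forward model, no artifacts (EOG/EMG), no
nonstationarity within trials, and only two spatial sources. Passing the
difference-only benchmark shows the pseudocovariance pathway works as
designed; it does not predict effect sizes on real recordings.

# Evaluation harness

Stratified 5-fold cross-validation repeated 30 times (defaults), with all
fold assignments drawn up-front from the seed so that different variants
and classifiers share identical folds (common random numbers — paired
comparisons remain valid). By default spatial filters and features are
re-fit inside every training fold (no leakage; a test asserts filter
invariance to test-fold labels); a fit-once compatibility switch exists
because the original protocol is ambiguous on this point. Built-in
classifiers are a 100-tree random forest (CART/gini, unlimited depth,
$\lfloor\sqrt p\rfloor$ features per split — authored in-package because
the runtime ships no classification library) and exact 1-NN; anything
else plugs in through a fit/predict contract.

Null calibration is checked by permuting labels on a *class-symmetric*
synthetic dataset: on separable data a single fixed permutation retains
$O(1/\sqrt n)$ correlation with the true labels and sits measurably above
50%, so chance-level behavior is a harness property only where the data
carry no class signal.

The significant-subject rule uses the exact one-sided binomial test: the
smallest $k$ with $P(X \ge k \mid n, 1/2) \le 0.05$, i.e. $\approx 64\%$
at $n = 45$ trials ($k = 29$), with the normal approximation available as
an option; subjects significant under *any* variant enter the pool
(union rule). Variant comparisons use a paired two-sided Student's t-test
by default (the source protocol does not state the flavor; both
alternatives are exposed).

# Asymmetry analysis

For each symmetric electrode pair (FC5-FC6, FC1-FC2, C3-C4, CP5-CP6,
P1-P2) and trial, the asymmetry index
$(\mathrm{CH}_L - \mathrm{CH}_R)/(\mathrm{CH}_L + \mathrm{CH}_R)$ is
computed for the mu−beta power difference and the mu+beta power sum,
where power is the variance of the IMF-reconstructed rhythm (mean
removed, consistent with the zero-mean preprocessing). Outliers beyond
mean ± 5 SD are removed in a single pass per (pair, quantity) group. On
the difference-only fixture the power-difference asymmetry separates the
classes by sign at the central pair while the power-sum asymmetry does
not — the desk-scale restatement of the hemispheric-dissociation finding
that motivates keeping the pseudocovariance.

# Numerical choices

* **Takagi via SVD + phase correction**: $P = U\Sigma V^H$, coupling
  $D = U^H\bar V$, $Y = U D^{1/2}$. Clusters of near-equal singular
  values ($\Delta < 10^{-8}\max$) take a blockwise principal square root
  of the unitary-symmetric block via its commuting real/imaginary parts.
* **Determinism conventions**: Takagi columns sign-fixed (largest-modulus
  entry has positive real part); covariance filter rows phase-normalized;
  pseudocovariance filter rows sign-normalized only (their congruence
  tolerates just ±1); eigenvalues sorted descending for class L.
* **Degeneracy handling**: ridge $10^{-10}\,\mathrm{tr}(C_c)/N$ when the
  condition number exceeds $10^{12}$; rank reduction at relative
  `rank_tol` $10^{-10}$; near-zero Takagi values (near-circular data) are
  pseudo-inverted to zero with a warning.
* **Epoching**: 0-based, half-open $[\text{onset}, \text{onset} + n)$
  windows, no pre-stimulus baseline.
* **Montage**: the default 14-channel layout is a *reconstruction* — the
  five named sensorimotor pairs plus four midline channels chosen to
  cover the scalp; it is fully overridable.

# Known limitations

* MEMD is $O(\text{directions} \times \text{samples} \times
  \text{iterations})$ in pure R; decomposing hundreds of trials is
  feasible but slow. The pipeline therefore also offers the zero-phase
  FFT band-pass route (which doubles as the independent oracle MEMD is
  tested against) and the ground-truth route for synthetic data.
* The EDF reader supports uniform-rate signals and TAL annotations only —
  enough for standard motor-imagery recordings, not a general EDF+
  implementation.
* Multiclass CSP extensions, ensemble EMD variants and topographic
  rendering are out of scope; pattern maps are exported as delimited text
  for external plotting.
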