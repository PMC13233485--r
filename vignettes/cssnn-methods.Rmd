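---
title: "Compressed-sensing spiking networks: model, training and hardware dataflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed-sensing spiking networks: model, training and hardware dataflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cssnn)
```

## The model

`cssnn` implements *compressed learning with spiking neurons*: instead of
reconstructing a sparse signal from its compressed measurements, the
classifier operates directly in the measurement domain, and the measurement
operator itself is learned for the classification task.

**Sensing.** A signal $x \in \mathbb{R}^n_{\ge 0}$ (flattened pixels,
normalized to $[0,1]$) is compressed by a binary measurement matrix
$B \in \{0,1\}^{m \times n}$ with $m \ll n$:
$\hat{x} = B x$. Each row of $B$ has exactly `Sample` ones — a fixed
per-measurement sensing budget — so a one means "this measurement samples
this pixel", not a weight contribution. The compression rate is
$\mathrm{CR} = m/n$ and the matrix sparsity is $\mathrm{Sample}/n$.
Because $B$ and $x$ are non-negative, the accumulation needs no sign
handling, which is what makes the scheme cheap in hardware.

$B$ is derived from a real trainable matrix $W \in [-1,1]^{m \times n}$ by
per-row top-$k$ selection: row $i$ of $B$ has ones exactly at the positions
of the `Sample` largest entries of row $i$ of $W$ (`binarize_rows()`), with
ties broken toward the lowest column index so the selection is
deterministic across platforms.

**Neurons.** All layers are discrete-time leaky integrate-and-fire (LIF)
units. With decay $d = e^{-\Delta t/\tau}$,

$$u_t = d\, v_{t-1} + I_t, \qquad
  s_t = \mathbf{1}[u_t \ge v_{th}], \qquad
  v_t = (1 - s_t)\, u_t + s_t\, v_{reset}.$$

Defaults are $v_{th} = 1$, $v_{reset} = 0$, $\tau = 2$, $\Delta t = 1$
(so $d \approx 0.60653$). The exponential leak is the default;
`lif_params(leak = "linear")` gives the $1 - \Delta t/\tau$ variant common
in SNN training frameworks, since published results in this area are often
produced with that approximation — both satisfy $0 < d < 1$. There is no
refractory period, and reset is hard.

**Network.** `build_network("784-cs78-fc64-fc10", sample = 78)` builds the
standard topology: the encoder layer receives the constant current
$\hat{x} = Bx$ at every timestep (static frames are re-applied each step;
event data supply one frame per step), and spikes propagate through the
fully connected LIF layers *within* the same timestep (zero inter-layer
latency). Classification aggregates output spikes over all timesteps and
takes the most active neuron, ties toward the lowest index
(`classify_by_votes()`; indices are 1-based in R).

## Co-optimization by spatio-temporal backpropagation

Training unrolls the dynamics over $T$ timesteps and backpropagates
through both space (layers) and time (the membrane recursion). The
non-differentiable spike is given the arctangent surrogate derivative

$$g(u - v_{th}) = \frac{\alpha}{2\left(1 + \left(\frac{\pi}{2}\alpha
  (u - v_{th})\right)^2\right)}, \qquad \alpha = 2,$$

which peaks at $\alpha/2$ at threshold. The hard-reset path stays in the
graph: $\partial v_t/\partial u_t = (1 - s_t) + (v_{reset} - u_t)\,
g(u_t - v_{th})$.

Two structural facts shape the encoder's gradient:

* the encoder current is *time-invariant*, so no temporal credit reaches
  the measurement matrix — its gradient is purely spatial, accumulated
  over timesteps;
* the forward pass uses the binary $B$, while updates apply to the real
  $W$. The default is a straight-through estimator onto the full $W$
  (`estimator = "ste"`); `estimator = "mask"` restricts gradients to the
  currently selected entries. STE is the default because unselected
  weights must receive signal to ever enter the top-$k$ set.

$B$ is re-derived from $W$ at every forward pass, and $W$ is clipped to
$[-1,1]$ after every optimizer step (an implicit regularizer that also
keeps the top-$k$ ranking bounded). The optimizer is AdamW
($\beta_1 = 0.9$, $\beta_2 = 0.999$, decoupled weight decay $0.01$), the
learning rate starts at $10^{-3}$ and is decayed by a fixed factor *per
epoch*.

The loss is not uniquely standard in this literature, so it is a
configuration choice: the default is cross-entropy on the time-averaged
output firing rates (`loss = "ce"`); mean squared error of rates against
one-hot targets (`loss = "mse"`) is also provided. Neither is claimed to
be anything but a sensible default.

**Gradient correctness.** The backward pass is verified against an exact
oracle: with `soft = TRUE` the forward replaces the Heaviside spike by
$\tilde{s}(z) = \tfrac12 + \arctan(\tfrac{\pi}{2}\alpha z)/\pi$, whose
exact derivative *is* the surrogate. On that smooth network the STBP
gradients must equal (and in the tests do equal, to $\sim 10^{-10}$)
central finite differences for every weight, including the encoder path
through the reset. The hard forward differs only in the spike values, so
this validates the full spatio-temporal chain rule honestly rather than
asserting a hand-derived formula against itself.

**Baseline.** With `encoder = "grm"` the first layer is a fixed Gaussian
random matrix and only the SNN layers train — the classical
compressed-learning baseline. `gaussian_baseline()` returns i.i.d.
$N(0,1)$ draws; when placed in a network the matrix is scaled by
$1/\sqrt{m}$ so the measurement energy matches the signal energy
(standard compressed-sensing normalization). This keeps the baseline's
encoder currents in the LIF dynamic range, i.e. the baseline is given a
fair chance.

## Post-training quantization

`quantize_network()` applies symmetric per-tensor fixed-point
quantization: weights to `weight_bits` (default 8) with the max-abs
element on the extreme positive code, rounding half away from zero
(bit-exact reproducible); the binary matrix needs no weight storage
beyond its indices. Membrane potentials get a per-layer grid in which
$v_{th}$ sits exactly at code $2^{\mathrm{mp\_bits}-2}$ — one headroom
bit above threshold — with saturation (not wraparound) at the
two's-complement bounds, matching hardware comparator semantics. Input
pixels are taken on the 8-bit $[0,255]$ grid.

Storage compression factors are reported as
$\mathrm{float\_bits}/\mathrm{bits}$ truncated to two decimals — a
deliberately conservative reporting convention, so 32→8-bit weights
report $4\times$ and 32→9-bit membrane potentials report $3.55\times$.
Resource-comparison *ratios* in `compare_encoder_methods()`, by contrast,
are rounded to two decimals; the two reporting conventions are
intentional and documented here once.

The deployment-accuracy figures quoted for quantization-aware training
methods are out of scope: this module is post-training only, and the test
suite asserts only that 8-bit quantization costs at most a few accuracy
points on the synthetic tasks.

## The index-matching dataflow simulator

The hardware-facing representation of $B$ is the relative index table
(`build_index_table()`): the coordinates of the ones sorted along the
pixel axis (ties by ascending neuron address), each pixel index stored as
the gap to the previously sampled pixel. Entries sharing a pixel are
adjacent with gap 0. Streaming pixels against this table
(`stream_cs_encode()`) needs one cycle per arriving pixel plus one per
table entry — $m \cdot \mathrm{Sample} + n$ cycles — and exactly
$m \cdot \mathrm{Sample}$ matrix reads; on integer pixel codes the result
equals $Bx$ bit for bit.

`simulate_inference()` walks the full processor state machine on a
quantized model: per timestep, streamed encoding, then an
address-ordered sweep of every layer in which a firing neuron is reset
and its outgoing weight column is accumulated into the post-neurons
(spike-driven processing: synaptic work happens only when pre-neurons
fire), a silent neuron just leaks; output spikes are tallied as votes.
Because the simulator performs the same fixed-point scalar operations as
the reference `quantized_forward()` (integer synaptic sums; one rounded
scale conversion per step; multiply-then-round leak), the dataflow is
*exactly* equivalent to the reference network — the central
hardware-correctness property, asserted bit-exactly in the tests across
random networks. What the simulator adds is exact cycle/read/write
counters, whose closed forms are in `predicted_rw_counts()`. Whether the
firing rate in those closed forms is a per-timestep or whole-inference
average is ambiguous in this literature; the analytic path takes the
whole-inference average, while the simulator sidesteps the question by
counting empirically. Aggregate read/write totals for a full benchmark
depend on accounting details (which state charges which counter,
timestep multiplicity), so the simulator logs its counters but the
package does not assert any particular published total.

One width convention deserves a note: the per-entry storage width of the
index table is a free parameter of `compare_encoder_methods()` (14 bits
reproduces the standard comparison point), while the model-size formula
`model_size_cs()` uses the addressing width
$\lceil \log_2 L_{in} \rceil$ per index. These coexist deliberately;
each reproduces its own printed convention. For the addressing width the
package always uses the ceiling: $L_{in} = 2312$ requires 12 bits — 11
bits can address only 2048 inputs — even though rounded
$\log_2$ values sometimes appear in hardware summaries.

## Synthetic data: what it emulates and what it does not

All tests run without downloads on generated data.

`gen_sparse_frames()` emulates the signal family compressed sensing
presumes: each class is a sparse linear combination of point basis
functions — a fixed random support of `k_active` pixels (default 20 of
784, with 4 pixels shared across all classes), uniform amplitudes in
$[0.5, 1]$, additive Gaussian noise ($\sigma = 0.02$) and clipping to
$[0,1]$. The support size is deliberately *truly sparse* rather than
matching a handwritten-digit ink fraction ($\approx 19\%$): with
$v_{th}$ fixed at 1 and `Sample` of order $0.1 n$, a 19%-dense signal
drives every encoder measurement far above threshold at every timestep,
saturating the spike channel and destroying the information the
classifier needs; sparse supports keep encoder currents in the LIF
dynamic range. Consequences for interpretation: passing tests show the
co-optimization and the hardware path work as specified on sparse
signals; they do not certify accuracy figures on natural image
benchmarks, which have correlated dense structure the generator does not
model.

`gen_event_frames()` emulates event-camera data: per timestep, a class's
spatial support fires Bernoulli(`event_rate`) on the ON polarity channel,
and the OFF channel fires (same rate) only where ON stayed silent, making
the polarities anti-correlated. Frames are flattened in (channel, row,
column) row-major order with channel slowest — documented because the
index table depends on the flattening. Real event streams' temporal
correlation and sensor noise are not modeled.

`read_idx()` parses the big-endian IDX container for the optional
real-data path; it returns raw 8-bit pixels (normalization is the
encoder's job).

## Desk-scale study conditions

The full-scale training protocol kept as `train_config()` defaults is:
AdamW, initial learning rate $10^{-3}$ decayed by $0.1$ per epoch, 64
epochs, batch size 18, $T = 100$ timesteps for frame data (10 for event
data), ATan $\alpha = 2$.

The package's own experiments (acceptance script, heavy tests) run at
desk scale: 10 classes × 60 samples (400 train / 200 test), $T = 20$,
20 epochs with per-epoch decay $0.8$. The decay factor is scaled by
optimizer steps, not copied: $0.1$ per epoch at thousands of minibatches
per epoch corresponds to a near-unity per-epoch factor at 23 minibatches
per epoch, and $0.8$ over 20 epochs gives a comparable decay per update.
These sizes were fixed once as the package's study conditions.

Under those conditions the acceptance script
(`scripts/acceptance.R`) trains the sparse-binary model
(`784-cs78-fc64-fc10`, CR $= 0.1$, sparsity $0.1$) and the GRM baseline,
measures empirical operation counts — encoder operations plus
firing-rate-weighted SNN operations, one MAC counted as two operations,
binary-encoder entries counted as single additions — and reports the
percentage reduction. The test suite additionally checks that the
learned model's accuracy is within two points of the baseline and that
accuracy degrades monotonically when CR drops to 0.01.

## Numerical choices and degenerate inputs

* Top-$k$ and vote ties break toward the lowest index; `order()` with an
  explicit secondary key makes this platform-independent.
* Rounding in the fixed-point path is half-away-from-zero everywhere.
* An all-zero tensor quantizes to scale 0 and zero codes (identity).
* An all-zero input yields all-zero rasters, class 1 by the tie rule and
  the analytic floor of the counters.
* `Sample = n` degenerates to an all-ones matrix (unpruned binary
  projection); a `Sample = 0` index table is the legal empty table.
* Non-finite training loss aborts with a diagnostic rather than
  continuing silently.
* Generators and fits are pure functions of their seeds; seeded helpers
  save and restore the caller's RNG state.

## Known limitations

* Training is plain R matrix code: fine for the desk-scale studies it is
  built for, not for ImageNet-scale sweeps.
* The simulator is behavioral: one cycle per FSM micro-operation, no
  pipelining, no SRAM banking, no energy model, and the byte-transport
  interface is abstracted away.
* Quantization is per-tensor and post-training only.
* The per-measurement budget is interpreted row-wise (one row = one
  measurement); a column-wise reading of the same constraint appears in
  parts of this literature and is not implemented.
* Event-mode encoder binarization is recomputed per timestep inside the
  forward loop; correct, but the main cost of event-mode training.
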