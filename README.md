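# VMDespeckle

Speckle — the granular, signal-dependent interference of coherent imaging —
is the dominant noise source in medical ultrasound. It blurs organ
boundaries and fine lesions, and it defeats plain smoothing filters because
the noise level rises with the signal. **VMDespeckle** implements a
frequency-division despeckling pipeline for single-channel ultrasound-style
images: the image is first split into band-limited sub-modes by
two-dimensional variational mode decomposition (2D-VMD), the number of
modes is chosen adaptively from a visual-information-fidelity (VIF)
criterion, and each band is then denoised with the spatial filter suited to
it — Perona–Malik anisotropic diffusion for the low-frequency mode that
carries the anatomy, two-stage BM3D collaborative filtering for the noisy
high-frequency modes — before the processed modes are summed back into the
image. It is aimed at researchers who need a tested, scriptable despeckler
and a reproducible synthetic benchmark (phantom generators, speckle
simulator, PSNR/SSIM evaluation) without any external data.

## The model

Speckle is simulated with the signal-dependent noise model

```
g(x) = f(x) + f(x)^n · η(x),        η ~ N(0, σ²) i.i.d.,  n = 0.5
```

(n = 1 gives the pure multiplicative model g = f(1+η); n = 0.5 matches
ultrasound data). Noise levels are swept by the variance v = σ² over
0.1–0.8.

2D-VMD finds K modes u_k, each spectrally compact around a center
frequency ω_k, by ADMM on

```
min Σ_k α_k ‖∇[u_AS,k(x) e^{-j⟨ω_k,x⟩}]‖²   s.t.  Σ_k u_k = f
```

with the spectral updates (half-plane analytic spectra)

```
û_k ← (f̂ − Σ_{i≠k} û_i + λ̂/2) / (1 + 2α_k|ω − ω_k|²)
ω_k ← ∫ ω |û_k(ω)|² dω / ∫ |û_k(ω)|² dω
λ̂  ← λ̂ + τ (f̂ − Σ_k û_k)
```

Mode 1 (smallest ‖ω_k‖) is given a wide band (small α) so it carries the
image structure; the remaining narrow modes carry edges and noise.

K is selected by decomposing at trial K, scoring every sub-mode against the
input with VIF (a Gaussian-scale-mixture mutual-information ratio computed
on 3×3 blocks of wavelet detail subbands), sorting the scores, and counting
adjacent differences δ ≤ 0.001: none → K+1, several → K−1, exactly one →
stop and use K−1. Over-decomposition shows up as near-duplicate modes with
nearly identical VIF.

## Worked example

```r
library(VMDespeckle)
f   <- makeCompositePhantom(size = 302, seed = 1)          # clean phantom
g   <- addSpeckle(f, sigma = sqrt(0.6), seed = 7)          # variance-0.6 speckle
res <- despeckle(g, k = 4, reference = f)
res
#> DespeckleResult: 302x302 image, K = 4
#>   BM3D sigma per high-frequency mode: 1.69, 2.84, 4.08
#>   vs reference: PSNR 37.65 dB, SSIM 0.9051 (noisy input: 31.14 dB)
```

The report says the pipeline raised PSNR from 31.14 dB (speckled input) to
37.65 dB and structural similarity to 0.91; the per-mode sigmas are the
noise levels BM3D estimated and removed from the three high-frequency
modes. With `k = "auto"` the same call first runs the VIF selection and
records its trace (`res@kselect_trace`).

A command-line front end with the same operations (phantom, simulate,
decompose, select-k, diffuse, bm3d, denoise, evaluate, sweep) is installed
at `inst/cli/vmdespeckle.R`:

```sh
Rscript inst/cli/vmdespeckle.R denoise --input G.png --k auto --output D.png --report report.json
```

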