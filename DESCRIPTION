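Package: eegsr
Title: Spatio-Temporal EEG Super-Resolution with Bidirectional Selective
    State-Space Diffusion Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs high-density, high-rate electroencephalography (EEG)
    from low-density or low-rate recordings. Implements a bidirectional
    selective state-space (Mamba) sequence backbone, a conditional denoising
    diffusion model with deterministic one-step sampling, and a regression
    variant of the same trunk, together with the surrounding pipeline:
    idealized 10-10 montage geometry, a synthetic band-limited EEG generator,
    bad-channel detection and spherical-spline interpolation, zero-phase FIR
    filtering, windowing and splitting, spatial/temporal degradation
    operators, and a reconstruction-fidelity metric suite (NMSE, PCC, SSIM,
    PSNR, SNR, topographic smoothness, band-power error, imaginary coherence,
    Frechet feature distance). Training uses hand-written reverse-mode
    gradients; everything runs seeded on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
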