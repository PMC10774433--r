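Package: fecgdenoise
Title: Adversarial Denoising of Multichannel Fetal Electrocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing noise from four-channel non-invasive fetal
    electrocardiogram (fECG) recordings with an adversarially trained
    convolutional encoder-decoder. Includes a synthetic paired-data simulator
    emulating physiological event cases (fetal movement, heart-rate
    acceleration, uterine contraction, ectopic beats) at controlled input SNR,
    a maternal-ECG template-subtraction canceller and windowing pipeline, the
    composite training objective (reconstruction, contractive Jacobian
    penalty, adversarial feature matching, latent consistency), a full
    evaluation metric suite (SNR improvement, RMSE, PRD, QRS-detection
    PPV/SE/F1 with +/-50 ms tolerance), a sym6/SureShrink wavelet baseline,
    and CSV/WFDB record input/output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
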