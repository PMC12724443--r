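Package: abrkit
Title: Auditory Brainstem Response Recording, Simulation and Threshold Analysis
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: Offline analysis toolkit for click-evoked auditory brainstem
    response (ABR) recordings from multi-channel differential electrode
    montages. Decodes 24-bit delta-sigma ADC sample frames to calibrated
    voltages, detects click stimuli on a recorded speaker channel, filters
    recordings into analysis bands, epochs and averages trials with
    ECG-driven outlier rejection, and quantifies responses with a rolling
    standard-deviation strength statistic from which hearing thresholds and
    hearing-loss threshold shifts are interpolated. Includes a seeded
    synthetic-session generator (1/f background, ECG, breathing artifacts,
    level-dependent ABR wavelets) so the full pipeline is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    rlang
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
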