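# Synthetic ECG presets (version 1).
#
# Beat morphologies: each wave is a Gaussian bump (amplitude mV, center s
# relative to the R peak, width s = Gaussian sigma). The four classes mirror
# the MIT-BIH target labels:
#   N  normal sinus beat: P-QRS-T with a narrow R wave
#   L  left bundle branch block: wide notched QRS (two merged R bumps),
#      absent Q, discordant (negative) T
#   R  right bundle branch block: rsR' double peak, inverted T
#   V  premature ventricular contraction: no P wave, wide tall QRS
#      (sigma >= 1.5x the N preset's R width), large discordant T
beat_morphologies:
  "N":
    noise_sd: 0.03
    waves:
      - {wave: P, amp:  0.15, center: -0.180, width: 0.025}
      - {wave: Q, amp: -0.10, center: -0.025, width: 0.010}
      - {wave: R, amp:  1.00, center:  0.000, width: 0.012}
      - {wave: S, amp: -0.20, center:  0.026, width: 0.010}
      - {wave: T, amp:  0.30, center:  0.220, width: 0.050}
  "L":
    noise_sd: 0.03
    waves:
      - {wave: P,  amp:  0.12, center: -0.180, width: 0.025}
      - {wave: R1, amp:  0.70, center: -0.012, width: 0.030}
      - {wave: R2, amp:  0.58, center:  0.045, width: 0.028}
      - {wave: S,  amp: -0.10, center:  0.110, width: 0.020}
      - {wave: T,  amp: -0.25, center:  0.260, width: 0.060}
  "R":
    noise_sd: 0.03
    waves:
      - {wave: P,  amp:  0.15, center: -0.180, width: 0.025}
      - {wave: r,  amp:  0.35, center: -0.030, width: 0.010}
      - {wave: s,  amp: -0.30, center:  0.004, width: 0.010}
      - {wave: Rp, amp:  0.90, center:  0.045, width: 0.018}
      - {wave: T,  amp: -0.20, center:  0.240, width: 0.050}
  "V":
    noise_sd: 0.03
    waves:
      - {wave: R, amp:  1.20, center:  0.010, width: 0.035}
      - {wave: S, amp: -0.40, center:  0.085, width: 0.030}
      - {wave: T, amp: -0.45, center:  0.300, width: 0.070}

# Rhythm strips: RR-interval model per class (seconds). jitter is the sd of
# Gaussian RR jitter for model "normal", or the half-width of uniform jitter
# for model "uniform". p_scale rescales the P-wave amplitude of the beat
# morphology (0 removes the P wave, as in atrial fibrillation). noise_sd is
# additive white noise in mV.
rhythm_specs:
  "N":     {beat: "N", duration: 30, fs: 300, mean_rr: 0.80, rr_model: normal,  jitter: 0.020, p_scale: 1.0, noise_sd: 0.02}
  "AF":    {beat: "N", duration: 30, fs: 300, mean_rr: 0.70, rr_model: uniform, jitter: 0.250, p_scale: 0.0, noise_sd: 0.02}
  "Other": {beat: "V", duration: 30, fs: 300, mean_rr: 1.25, rr_model: normal,  jitter: 0.050, p_scale: 1.0, noise_sd: 0.02}
  "Noisy": {beat: "N", duration: 30, fs: 300, mean_rr: 0.80, rr_model: normal,  jitter: 0.020, p_scale: 1.0, noise_sd: 0.50}
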