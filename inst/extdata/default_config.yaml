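# Default per-paradigm analysis parameters. Values mirror the built-in
# defaults of analysis_config(); edit a copy and load it with
# load_analysis_config() to override them.
reference: Cz
alpha_level: 0.05
paradigms:
  resting:
    filter: {highpass_hz: 1, lowpass_hz: 100, notch_hz: 50}
    window_s: 8
  alpha_block:
    filter: {highpass_hz: 1, lowpass_hz: 100, notch_hz: 50}
    window_s: 2
    closed_label: eyes_closed
    open_label: eyes_open
    settle_s: 2
    alpha_band: [8, 12]
  assr:
    filter: {highpass_hz: 1, lowpass_hz: 100, notch_hz: 50}
    window_s: 8
    f0: 40
    band: [35, 45]
  ssvep:
    filter: {highpass_hz: 1, lowpass_hz: 100, notch_hz: 50}
    window_s: 8
    f0: 10
    band: [5, 15]
  aep:
    filter: {highpass_hz: 1, lowpass_hz: 20, notch_hz: null}
    epoch_window: [-0.1, 0.5]
    baseline: [-0.1, 0]
    latency_correction: 0         # auditory chain: 0 ms measured delay
    stim_label: stim
    components: [P1, N1, P2]
  vep:
    filter: {highpass_hz: 1, lowpass_hz: 20, notch_hz: null}
    epoch_window: [-0.1, 0.5]
    baseline: [-0.1, 0]
    latency_correction: 0.021     # visual chain: 21 ms measured delay
    stim_label: stim
    components: [P1, N1, P2]
  aep_oddball:
    filter: {highpass_hz: 1, lowpass_hz: 20, notch_hz: null}
    epoch_window: [-0.1, 0.5]
    baseline: [-0.1, 0]
    latency_correction: 0
    components: [MMN]
  vep_oddball:
    filter: {highpass_hz: 1, lowpass_hz: 20, notch_hz: null}
    epoch_window: [-0.1, 0.8]
    baseline: [-0.1, 0]
    latency_correction: 0.021
    components: [P300]
  eog:
    saccade_filter: {highpass_hz: 1, lowpass_hz: 20, notch_hz: null}
    blink_filter: {highpass_hz: 0.2, lowpass_hz: 3, notch_hz: null}
    saccade_window: [-0.1, 0.5]
    blink_window: [-1, 2]
    baseline: [-0.1, 0]
    latency_correction: 0.021
    assessment_time: 0.2
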