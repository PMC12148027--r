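# Default magnitudes for the synthetic gait cohort. None of these numbers are
# measured values; they are invented, field-realistic defaults. The impairment
# multipliers are set so that their across-impairment averages reproduce the
# inflation levels the analysis is designed to detect (step-time SD +53%,
# step-width SD +54%, mean step width +30% on average across impairments).
n_subjects: 10
conditions: [normal, ankle_braces, eyes_blocked, pneumatic_jets]
unimpaired_condition: normal
treadmill_speed: 1.25        # m/s
steady_trial_duration: 180   # s
mean_step_width: 0.12        # m
mean_step_time: 0.55         # s
step_time_asymmetry: 0.008   # s, half the left/right mean step-time split
stance_fraction: 0.65        # stance duration as a fraction of stride time
step_width_sd: 0.0251        # m, unimpaired per-step SD (base subject)
step_time_sd: 0.016          # s
placement_residual_sd: 0.012 # m, SD about the linear foot-placement law
placement_gain_position: 1.3 # dimensionless, law gain on ML CoM position
placement_gain_velocity: 0.25  # s, law gain on ML CoM velocity
com_midstance_speed: 0.15    # m/s, mean ML CoM speed toward the swing side
com_midstance_speed_sd: 0.05 # m/s
inter_subject_sd:
  step_width: 0.02           # m, spread of per-subject mean step width
  step_time: 0.03            # s, spread of per-subject mean step time
  placement_noise: 0.003     # m, spread of per-subject placement residual SD;
                             # the implied relative scale (SD/0.012 = 0.25)
                             # also scales each subject's other noise magnitudes
divergence_rate: 0.35        # 1/stride, injected short-term divergence, unimpaired
c7_periodic_amplitude: [0.18, 0.10, 0.14]  # m/s per axis
c7_deviation_amplitude: 0.25 # m/s, stride-to-stride chaotic component; kept
                             # dominant over other stride-varying components
                             # so the injected divergence governs the
                             # estimator's short-term slope
c7_noise_sd: 0.002           # m/s, additive white measurement noise
impairment_multipliers:      # multiplicative, relative to the same subject's baseline
  ankle_braces:
    step_width_sd: 1.35
    step_time_sd: 1.40
    placement_sd: 1.30
    divergence: 1.25
    mean_step_width: 1.25
    com_response: 1.15
  eyes_blocked:
    step_width_sd: 1.50
    step_time_sd: 1.50
    placement_sd: 1.50
    divergence: 1.35
    mean_step_width: 1.35
    com_response: 1.40
  pneumatic_jets:
    step_width_sd: 1.77
    step_time_sd: 1.69
    placement_sd: 1.80
    divergence: 1.45
    mean_step_width: 1.30
    com_response: 0.85
perturbations:
  count: 16
  magnitudes_pct_bw: [7.5, 15]
  duration_s: 0.3
  directions: [forward, backward, leftward, rightward]
  spacing_s: [25, 30]        # uniform inter-onset spacing
com_response_displacement: 0.05  # m, ML CoM displacement at the next ipsilateral
                                 # midstance after a 7.5% BW lateral perturbation
stutter_probability:         # probability of one stutter step in a recovery
  ml_high: 0.16
  ml_low: 0.008
  fa_high: 0.025
  fa_low: 0.002
marker_rate: 100             # Hz
force_rate: 1000             # Hz
drift_per_min:               # optional linear drift of generator parameters
  step_time_sd: 0.0          # s/min
  step_width_sd: 0.0         # m/min
  mean_step_width: 0.0       # m/min
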