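# Demo configuration: small synthetic 2x2 study, all stages.
seed: 11
n_per_group: 3
modalities: [calcium, striation]
stages: [simulate, sarcomere, calcium, stats]
snr_db: 20
pixel_size_um: 0.1
sampling_hz: 50
duration_s: 20
pacing_hz: 0.5
band_um: [1.2, 3.0]
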