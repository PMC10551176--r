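# Small-scale dataset for desk experiments: 500 frames of 64 x 64,
# 400 train / 100 test, 4:1 smoke-free:smoke in each split.
total: 500
smoke_fraction: 0.2
test_fraction: 0.2
height: 64
width: 64
intensity_range: [0.3, 1.0]
density_range: [0.3, 0.9]
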