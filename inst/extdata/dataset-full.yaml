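# Full-scale synthetic dataset: 5,000 frames of 384 x 192, one fifth
# smoke-composited, stratified 3,800 train / 1,200 test (4:1
# smoke-free:smoke in each split).
total: 5000
smoke_fraction: 0.2
test_fraction: 0.24
height: 192
width: 384
intensity_range: [0.3, 1.0]
density_range: [0.3, 0.9]
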