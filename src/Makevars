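# No FP contraction: keystream trajectories must be reproducible bit-for-bit
# against the plain-R oracle (chaotic amplification turns 1 ulp into O(1)).
PKG_CXXFLAGS = -ffp-contract=off
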