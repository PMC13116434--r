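# PLACEHOLDER occurrence-level scheme (nests per hectare).
# The national grading standard's cut-offs are not reproduced here; these
# illustrative bounds exist only so the classification machinery can be
# demonstrated and tested. Supply your own scheme for real surveys.
# Intervals are closed below, open above; the top level is unbounded.
none_detected: [0, 1.0e-9]
I: [1.0e-9, 10]
II: [10, 50]
III: [50, 100]
IV: [100, .inf]
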