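# Approximate breakpoint spans of the polymorphic An. funestus inversions
# on the AfunF3 chromosome-arm assembly (1-based inclusive coordinates).
# Breakpoints are estimated from physically mapped markers, not molecular
# characterisation; treat them as configuration, not ground truth.
inversions:
  - name: 2Ra
    contig: 2R
    start: 25967767
    end: 33984223
  - name: 3Ra
    contig: 3R
    start: 1866360
    end: 11289547
  - name: 3Rb
    contig: 3R
    start: 20512400
    end: 33000000
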