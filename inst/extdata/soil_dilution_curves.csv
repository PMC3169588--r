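# Linear regressions of CT on log10(ng DNA template) for the serial dilution
# series (10, 5, 2.5, 1, 0.5 ng per well) of the five validation soils:
# CT = slope * log10(quantity) + intercept.
sample,slope,intercept
858,-3.61,29.86
1012,-3.24,31.06
1051,-3.60,31.84
1101,-4.47,29.55
1143,-4.37,30.94
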