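# Measured intensity levels from a representative BF tomogram
# (lower intensity = more scattering).
component,intensity
granule_peak,0.3
granule_inclusive,3.0
ribosome_peak,5.3
ribosome_inclusive,7.5
water,16
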