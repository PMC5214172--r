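# Example scanner-phantom source certificate (synthetic values with the
# nominal datasheet figures of a sealed Ge-68/Ga-68 scanner source).
source_id: XC-EXAMPLE-P01
nuclide: Ge-68
reference_datetime: 2013-03-03T00:00:00Z
reference_activity_mbq: 20.0
reference_concentration_kbq_ml: 250.0
stated_uncertainty: 0.025      # +/-2.5% at 95% confidence
active_diameter_mm: 45
active_height_mm: 45
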