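# Example dose-calibrator source certificate (synthetic values with the
# nominal datasheet activity of a sealed Ge-68/Ga-68 syringe-style source).
# The Ge-68 -> F-18 response factor is NOT part of the certificate schema:
# it is supplied separately per dose-calibrator model by the manufacturer.
source_id: XC-EXAMPLE-D01
nuclide: Ge-68
reference_datetime: 2013-03-03T00:00:00Z
reference_activity_mbq: 0.90
stated_uncertainty: 0.025
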