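# Cognitive test battery: test: domain, direction
# direction 'higher' means larger raw scores indicate better performance
digit_span: attention, higher
spatial_span: attention, higher
symbol_digit: processing_speed, higher
symbol_search: processing_speed, higher
trail_making_a: processing_speed, lower
verbal_fluency: executive_function, higher
design_fluency: executive_function, higher
trail_making_b: executive_function, lower
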