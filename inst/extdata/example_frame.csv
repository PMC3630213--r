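"origin_x_px","origin_y_px","tip_x_px","tip_y_px"
39,4,39,74
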