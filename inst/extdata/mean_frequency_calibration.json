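{"n_frames":512,"fs":100,"n_reps":200,"seed":20230928}
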