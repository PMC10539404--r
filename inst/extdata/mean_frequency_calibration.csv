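"tau_s","mean_frequency_hz"
0.004,23.429875
0.0049881125,22.306062
0.0062203166,21.127556
0.0077569098,19.409488
0.0096730847,17.824973
0.012062609,16.075585
0.015042412,14.328501
0.018758311,12.607114
0.023392142,11.251142
0.029170659,9.7868623
0.036376632,8.5529162
0.045362684,7.3526569
0.056568542,6.3215279
0.070542564,5.4622306
0.087968561,4.5806743
0.10969927,3.9779713
0.13679808,3.4874079
0.17059105,2.9769003
0.21273184,2.5856321
0.26528258,2.2669468
0.33081484,2.0338228
0.41253542,1.7380729
0.51444327,1.530752
0.64152522,1.4348942
0.8,1.3323741
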