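>seed_repeat_1 synthetic ankyrin-repeat instance
GNTPLHLAAKNGHLEIVKLLLDAGADVNAQDKF
>seed_repeat_2 synthetic ankyrin-repeat instance
GNTALHFAARNGHLDVVKLLLEAGADVNAQDKW
>seed_repeat_3 synthetic ankyrin-repeat instance
GETPLHLAAKNGHAEIVRLLLDKGADVNARDKF
>seed_repeat_4 synthetic ankyrin-repeat instance
GNTPLHVAASNGHLEIVELLLKAGADPNAQDKF
>seed_repeat_5 synthetic ankyrin-repeat instance
DNTPLHLAVKNGHLEVVKLLVDAGADVNLQNKF
>seed_repeat_6 synthetic ankyrin-repeat instance
GNSPLHLAAKEGHLEIVKLLLDAGAKVNAQDKF
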