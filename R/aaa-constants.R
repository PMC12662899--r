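# Shared front-end constants (in their own file so every module can rely
# on them at load time).

FRAME_RATE_HZ <- 16000
FRAME_LEN_S <- 0.96
FRAME_HOP_S <- 0.48
FRAME_LEN <- 15360L  # 0.96 s @ 16 kHz
FRAME_HOP <- 7680L
STFT_WIN <- 400L     # 25 ms
STFT_HOP <- 160L     # 10 ms
STFT_NFFT <- 512L
N_MEL <- 64L
MEL_FMIN <- 125
MEL_FMAX <- 7500
LOG_OFFSET <- 0.001
N_STFT_STEPS <- 96L
SUBFRAME_S <- 0.16
N_SUBFRAMES <- 6L
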