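PKG_CPPFLAGS = -DTMB_LIB_INIT=R_init_acclimtol -DTMB_EIGEN_DISABLE_WARNINGS -DTMBAD_FRAMEWORK
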