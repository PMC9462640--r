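motor_program	synthetic motor-control set	gene0001	gene0002	gene0003	gene0004	gene0005
cerebellar_signalling	synthetic cerebellar set	gene0003	gene0006	gene0007	gene0008
housekeeping	synthetic background set	gene0010	gene0011	gene0012	gene0013	gene0014	gene0015
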