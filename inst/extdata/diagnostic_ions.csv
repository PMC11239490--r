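motif,mz,tolerance
Neu5Ac,290.0881,0.5
Neu5Gc,306.0831,0.5
Fuc,145.0506,0.5
sulfate,96.9601,0.5
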