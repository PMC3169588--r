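name	sequence	orientation
FF390	CGATAACGAACGAGACCT	forward
FR1	AICCATTCAATCGGTAIT	reverse
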