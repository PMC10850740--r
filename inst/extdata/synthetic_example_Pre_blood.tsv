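cdr3_amino_acid	templates	frame_type
CASSLGETQYF	612	In
CASRDRGNTIYF	148	In
CSARDLNEQFF	97	In
CASSPGQGYEQYF	55	In
CASS*RTEAFF	23	Stop
CASSLRGNQPQHF	11	In
CAWSVSDLAKNIQYF	6	In
CASSYSTGDEQFF	3	In
CASRGLAGGYNEQFF	1	In
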