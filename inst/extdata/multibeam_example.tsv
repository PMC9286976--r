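# Annotated example of the reconstructed multibeam monitor dialect.
# Tab-delimited columns: t_s (seconds since assay start), tube_id (1-16),
# position_index (1-17; empty or NA when no beam fired that second).
# Timestamps must be strictly increasing within each tube at a 1 s period;
# missing seconds inherit the previous position (hold-last), and a gap longer
# than 5 s flags the fly for exclusion.
t_s	tube_id	position_index
0	1	1
1	1	2
2	1	2
3	1	5
4	1	NA
5	1	6
0	2	17
1	2	13
2	2	13
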