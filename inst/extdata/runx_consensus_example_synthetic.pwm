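# Illustrative RUNX-family consensus-derived position weight matrix
# (AACCACAGCA with a 0.001 pseudocount per cell). This is a synthetic
# example matrix for demonstrations and tests, not a published matrix.
# Columns: A C G T; one row per motif position.
0.997011952 0.000996016 0.000996016 0.000996016
0.997011952 0.000996016 0.000996016 0.000996016
0.000996016 0.997011952 0.000996016 0.000996016
0.000996016 0.997011952 0.000996016 0.000996016
0.997011952 0.000996016 0.000996016 0.000996016
0.000996016 0.997011952 0.000996016 0.000996016
0.997011952 0.000996016 0.000996016 0.000996016
0.000996016 0.000996016 0.997011952 0.000996016
0.000996016 0.997011952 0.000996016 0.000996016
0.997011952 0.000996016 0.000996016 0.000996016
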