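# 10-node worked-example network: one critical node (v1), six intermittent
# nodes (v4 v5 v6 v8 v9 v10) and three redundant nodes (v2 v3 v7); exactly
# four minimum dominating sets of size four.
v1	v4
v1	v5
v1	v6
v4	v2
v5	v2
v5	v3
v6	v3
v4	v7
v6	v7
v4	v8
v8	v4
v5	v9
v9	v5
v6	v10
v10	v6
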