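29b67220f370cf942f43df527b6149ba7dc8a0b490fd9b3ea970af4562062084 table1_study_countries.csv
fb70c60ada3e1fa53c0d52089de833ddde57a3baac7de3d790d5e952946ec632 table2_index_ranking.csv
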