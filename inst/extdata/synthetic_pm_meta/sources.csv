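source_id,source_kind,extraction_method,solvent
S01,extraction-study,sonication,water
S02,database,,
S03,literature-compilation,,
S04,extraction-study,crude solvent,acetone
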