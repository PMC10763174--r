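child_id,parent_id,relation
s2m,s2,modified
s3m,s3,modified
s6m,s6,modified
s7m,s7,modified
s9m_ssri,s9,split
s9m_maoi,s9,split
s10m,s10,modified
s11m,s11,modified
s12m,s12,modified
s13m,s13,modified
s16m,s16,modified
s17m,s17,modified
s19m,s19,modified
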