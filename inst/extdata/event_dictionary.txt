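# Event dictionary: one [event group] block, one MedDRA preferred term
# per line (matched case-insensitively, exact PT string).  The umbrella
# group coagulation_dysfunction contains every subgroup PT plus broader
# coagulation terms.  Best-effort defaults, not licensed MedDRA content.

[thrombocytopenia]
Thrombocytopenia
Platelet count decreased

[hypofibrinogenaemia]
Hypofibrinogenaemia
Blood fibrinogen decreased
Afibrinogenaemia

[coagulopathy]
Coagulopathy
Blood coagulation disorder
Disseminated intravascular coagulation

[aptt_prolonged]
Activated partial thromboplastin time prolonged

[inr_increased]
International normalised ratio increased

[pt_prolonged]
Prothrombin time prolonged

[coagulation_dysfunction]
Thrombocytopenia
Platelet count decreased
Hypofibrinogenaemia
Blood fibrinogen decreased
Afibrinogenaemia
Coagulopathy
Blood coagulation disorder
Disseminated intravascular coagulation
Activated partial thromboplastin time prolonged
International normalised ratio increased
Prothrombin time prolonged
Coagulation time prolonged
Hypocoagulable state
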