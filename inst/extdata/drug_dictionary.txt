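# Drug dictionary: one [label] block per drug of interest, one generic or
# brand name pattern per line.  Patterns are matched case-insensitively on
# word boundaries against both the verbatim drugname and the active
# ingredient field.  Best-effort defaults; replace with study-specific
# search terms for production analyses.

[tigecycline]
tigecycline
tygacil

[vancomycin]
vancomycin
vancocin
firvanq
vancoled

[linezolid]
linezolid
zyvox
zyvoxid

[daptomycin]
daptomycin
cubicin

[meropenem]
meropenem
merrem
meronem

[imipenem-cilastatin]
imipenem
primaxin
tienam

[cefoperazone]
cefoperazone
sulperazon
cefobid
cefamandole
mandol
cefotetan
cefotan
cefmetazole
zefazone
latamoxef
moxalactam
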