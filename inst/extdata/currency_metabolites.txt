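# Ubiquitous cofactors excluded from metabolite-level association testing.
# Base ids (compartment-agnostic); override with your own file if needed.
atp
adp
amp
nad
nadh
nadp
nadph
fad
fadh2
coa
h
h2o
pi
ppi
co2
o2
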