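# One abbreviation per line; a terminal period here never ends a sentence.
# Lines starting with '#' are comments. Matching is case-insensitive.
e.g.
i.e.
et al.
vs.
cf.
ca.
approx.
fig.
figs.
no.
vol.
dr.
prof.
st.
resp.
spp.
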