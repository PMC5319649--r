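# Curated floral-scent reference list: volatiles recorded from intact
# flowers, compiled from the floral-scent compendium literature. One
# compound name per line; matching is case-insensitive and
# whitespace-normalized. Edit to match the naming of your spectral library.
nonanal
decanal
octanal
heptanal
benzaldehyde
benzyl alcohol
phenylethyl alcohol
2-phenylethanol
phenylacetaldehyde
methyl salicylate
methyl benzoate
benzyl acetate
linalool
geraniol
nerol
citronellol
alpha-pinene
beta-pinene
limonene
myrcene
ocimene
alpha-terpineol
eucalyptol
1,8-cineole
pulegone
actinidine
trans-jasmone
jasmone
methyl jasmonate
eugenol
vanillin
anethole
estragole
indole
caryophyllene
alpha-farnesene
beta-farnesene
nerolidol
farnesol
tetradecanoic acid
hexadecanoic acid
(Z)-9-hexadecenoic acid
6-methyl-5-hepten-2-one
2-undecanone
gamma-decalactone
benzyl benzoate
p-cresol
guaiacol
coniine
sarracenin
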