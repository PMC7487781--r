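# Fully synthetic toy locus for examples and tests; running on a real locus
# requires a user-supplied reference FASTA and guide/donor sequences.
reference: synthetic_reference.fa
protospacer: GCGTCATAGCCAATGATTAC
pam: NGG
window: 3
donor: synthetic_donor.fa
primary_edit: nearest-to-cut
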