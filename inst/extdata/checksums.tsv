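file	md5
abec11_epitope_motifs.tsv	e0934244cd10b3d255618e366345be0e
abec11_channel_contacts.tsv	aaa8920f56c80d59a3a2b73d46930ae9
abec11_antibody_contacts.tsv	0e635a8ad7a7c2a656f15020afabd219
abec11_residual_conductance.tsv	24ce286401afa30571167252ed2ce3a2
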