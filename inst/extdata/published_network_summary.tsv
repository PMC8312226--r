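# Transcribed printed summary values of the three tick-microbiota co-occurrence
# networks (control/mock, keystone-vaccinated, non-keystone-vaccinated) from a
# published anti-tick-microbiota vaccination study; used as a worked-example
# fixture. keystone_eigenvector is the reported eigenvector centrality of the
# keystone taxon in the control and keystone-vaccinated networks (not reported
# for the non-keystone network). Removal fractions are the reported proportions
# of nodes removed at 0.90 connectivity loss.
network	nodes	edges	positive_edges	negative_edges	keystone_eigenvector	random_removal_fraction	directed_removal_fraction
control	525	2930	2159	771	0.95	0.58	0.23
keystone_vaccinated	518	910	723	187	0.01	0.55	0.14
nonkeystone_vaccinated	503	7098	3862	3228	NA	0.66	0.53
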