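site	raw	merged	quality_trim	mapping	chimera_removal	taxonomic_assignment
a	859156	496181	389859	251400	250725	32673
ab	754781	479497	433506	151744	151422	21989
b	587445	368095	304991	168274	167810	38316
c	458635	294565	247769	144850	144453	37659
cd	770055	512041	411234	176874	176231	36509
d	664475	444870	392865	187002	186445	21783
e	673495	364002	330412	172045	171389	20376
f	1238917	740208	621210	311638	310375	31035
mock	421868	92934	82218	67983	67983	57641
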