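category	subtype	shape	fill	glyph
component	protein	roundrectangle	#FFCC99
component	protein_complex	octagon	#FFCC00
component	gene_dna	parallelogram	#99CC00
component	rna	trapezoid	#CCFFCC
component	pathogen	triangle	#FF6666
component	drug	rectangle	#FF99CC
component	other_molecule	rectangle	#E8E8E8
process	binding	ellipse	#A8A8A8	B
process	dissociation	ellipse	#B8B8B8	D
process	phosphorylation	ellipse	#9999FF	P
process	ubiquitination	ellipse	#CC99FF	Ub
process	cleavage	ellipse	#FF9999	X
process	translocation	ellipse	#99CCFF	T
process	transcription	ellipse	#66CC66	TR
process	sink	ellipse	#333333	Ø
process	pathway_module	roundrectangle	#CCCCFF	M
process	other_process	ellipse	#D8D8D8
boolean	and	diamond	#FFFFFF	&
boolean	or	diamond	#FFFF99	OR
edge_annotation	catalysis	hexagon	#CCFFFF	C
edge_annotation	inhibition	hexagon	#FFCCCC	I
edge_annotation	other_annotation	hexagon	#EEEEEE
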