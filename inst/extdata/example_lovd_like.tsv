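gene	hgvs_c	significance	times_reported	flagged
GENE1	c.805G>A	Pathogenic	2	false
GENE1	c.163C>T	Likely pathogenic	1	false
GENE1	c.800T>C	Pathogenic	1	false
GENE1	c.649A>G	Likely pathogenic	2	false
GENE1	c.768A>C	Pathogenic/Likely pathogenic	1	false
GENE1	c.806T>A	Pathogenic/Likely pathogenic	1	false
GENE1	c.400T>G	Pathogenic	1	false
GENE1	c.196dup	Pathogenic	5	false
GENE1	c.521_523del	Likely pathogenic	4	false
GENE1	c.96dup	Pathogenic	2	false
GENE1	c.6_7insG	Pathogenic	1	false
GENE1	c.450A>T	Uncertain significance	2	false
GENE1	c.149C>G	Uncertain significance	1	false
GENE1	c.224T>A	Uncertain significance	4	false
GENE1	c.267C>G	Uncertain significance	2	false
GENE1	c.639G>A	Uncertain significance	1	false
GENE1	c.465C>G	Uncertain significance	2	false
GENE1	c.811A>G	Likely benign	1	false
GENE1	c.226C>G	Likely benign	1	false
GENE1	c.662T>G	Benign	1	false
GENE1	c.196T>A	Likely benign	2	false
GENE1	c.664C>T	Benign/Likely benign	4	false
GENE1	c.456G>A		3	false
GENE1	c.166C>T		1	false
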