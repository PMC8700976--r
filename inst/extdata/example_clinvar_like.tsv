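gene	hgvs_c	significance	times_reported	flagged
GENE1	c.654G>A	Likely pathogenic	1	false
GENE1	c.493+1G>A	Pathogenic/Likely pathogenic	2	false
GENE1	c.542T>C	Likely pathogenic	5	false
GENE1	c.768A>C	Pathogenic/Likely pathogenic	1	false
GENE1	c.544A>T	Pathogenic/Likely pathogenic	1	false
GENE1	c.268C>A	Pathogenic	4	false
GENE1	c.491G>T	Pathogenic/Likely pathogenic	1	false
GENE1	c.400T>G	Pathogenic	1	false
GENE1	c.473_475del	Pathogenic/Likely pathogenic	1	false
GENE1	c.109_110insA	Likely pathogenic	1	false
GENE1	c.521_523del	Likely benign	1	false
GENE1	c.96dup	Benign	5	false
GENE1	c.6_7insG	Benign	4	false
GENE1	c.450A>T	Benign/Likely benign	2	false
GENE1	c.551T>C	Uncertain significance	4	false
GENE1	c.795C>A	Uncertain significance	1	false
GENE1	c.240T>G	Uncertain significance	1	false
GENE1	c.34C>G	Uncertain significance	3	false
GENE1	c.587C>G	Uncertain significance	2	false
GENE1	c.707A>T	Benign	2	false
GENE1	c.698A>T	Likely benign	3	false
GENE1	c.226C>G	Benign	2	false
GENE1	c.525G>A	Likely benign	1	false
GENE1	c.166C>T		1	false
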