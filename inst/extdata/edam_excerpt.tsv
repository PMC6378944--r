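id	label	branch	parents
operation:0004	Operation	operation	
operation:0335	Formatting	operation	operation:0004
operation:3631	Peptide identification	operation	operation:0004
operation:3646	Peptide database search	operation	operation:3631
operation:3648	Validation of peptide-spectrum matches	operation	operation:3631
operation:3767	Protein identification	operation	operation:0004
operation:3633	Retention time prediction	operation	operation:0004
operation:3645	PTM identification	operation	operation:0004
operation:2436	Gene-set enrichment analysis	operation	operation:0004
operation:3630	Protein quantification	operation	operation:0004
operation:3635	Labeled quantification	operation	operation:3630
operation:3639	iTRAQ	operation	operation:3635
data:0006	Data	data	
data:0943	Mass spectrometry spectra	data	data:0006
data:0944	Peptide identification	data	data:0006
data:0945	Protein identification	data	data:0006
data:1501	Amino acid index	data	data:0006
data:1506	Amino acid index (hydropathy)	data	data:1501
data:2600	Pathway or network	data	data:0006
data:0928	Gene expression profile	data	data:0006
data:2901	Protein accession list	data	data:0006
format:1915	Format	format	
format:3712	Thermo RAW	format	format:1915
format:3244	mzML	format	format:1915
format:3654	mzXML	format	format:1915
format:3651	Mascot generic format (MGF)	format	format:1915
format:3702	MS2	format	format:1915
format:3653	DTA	format	format:1915
format:3655	pepXML	format	format:1915
format:3247	mzIdentML	format	format:1915
format:3711	X! Tandem XML	format	format:1915
format:3747	protXML	format	format:1915
format:3475	Tabular (TSV)	format	format:1915
format:3752	CSV	format	format:1915
format:2330	Textual format	format	format:1915
format:3464	JSON	format	format:1915
format:2331	HTML	format	format:1915
format:3997	Search results archive	format	format:1915
topic:0003	Topic	topic	
topic:0121	Proteomics	topic	topic:0003
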