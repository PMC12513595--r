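# synonym -> canonical drug name lexicon (deterministic stand-in for NLP-based name standardization)
synonym	canonical
obinutuzumab	obinutuzumab
gazyva	obinutuzumab
gazyvaro	obinutuzumab
ga101	obinutuzumab
ga-101	obinutuzumab
ro5072759	obinutuzumab
rituximab	rituximab
rituxan	rituximab
mabthera	rituximab
bendamustine	bendamustine
treanda	bendamustine
bendeka	bendamustine
venetoclax	venetoclax
venclexta	venetoclax
ibrutinib	ibrutinib
imbruvica	ibrutinib
chlorambucil	chlorambucil
leukeran	chlorambucil
methotrexate	methotrexate
mycophenolate mofetil	mycophenolate mofetil
cellcept	mycophenolate mofetil
prednisone	prednisone
allopurinol	allopurinol
zyloprim	allopurinol
cyclophosphamide	cyclophosphamide
cytoxan	cyclophosphamide
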