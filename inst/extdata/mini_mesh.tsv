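descriptor	address
Humans	B01.050.150.900.649.801.400.112.400.400
Persons	M01
Adult	M01.060.116
Child	M01.060.406
Aged	M01.060.116.100
Infant	M01.060.703
Pregnant Women	M01.975
Health Personnel	M01.526.485
Animals	B01.050
Mice	B01.050.150.900.649.313.992.635.505.500
Rats	B01.050.150.900.649.313.992.635.505.700
Dogs	B01.050.150.900.649.313.750.377.250
Zebrafish	B01.050.150.900.493.817.986
Drosophila melanogaster	B01.050.500.131.365.265.310.200
Caenorhabditis elegans	B01.050.500.500.294.400.875.500.200
Macaca mulatta	B01.050.150.900.649.801.400.112.199.500
Swine	B01.050.150.900.649.313.875.141.819
Cells, Cultured	A11.251.210
HeLa Cells	A11.251.860.180.370
Fibroblasts	A11.329.228
Neurons	A11.671
Stem Cells	A11.872
Archaea	B02
Escherichia coli	B03.440.450.425.325.300
Bacteria	B03
Viruses	B04
HIV-1	B04.820.650.589.650.350.350
Protein Conformation	G02.111.570.820.709.610
Base Sequence	G02.111.570.080.708.100
Phosphorylation	G02.149.704
Glycolysis	G02.149.440
Neoplasms	C04
Breast Neoplasms	C04.588.180
Diabetes Mellitus	C18.452.394.750
Cardiovascular Diseases	C14
Alzheimer Disease	C10.228.140.380.100
Hypertension	C14.907.489
Asthma	C08.127.108
Rodent Diseases	C22.795
Foot-and-Mouth Disease	C22.005
Drug Therapy	E02.319
Surgical Procedures, Operative	E04
Magnetic Resonance Imaging	E01.370.350.825.500
Immunotherapy	E02.095.520
Biopsy	E01.370.225.500.098
Transplantation	E04.936
Equipment and Supplies	E07
Surgical Instruments	E07.858
Antineoplastic Agents	D27.505.954.248
Proteins	D12.776
DNA	D13.444.308
Antibodies, Monoclonal	D12.776.124.486.485.114.224
Glucose	D09.400.105.450
Disease Models, Animal	C22.196
Disease Models, Animal	E05.598.500.496
Tumor Cells, Cultured	A11.251.860.900
Tumor Cells, Cultured	C04.557.337
Geographic Locations	Z01
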