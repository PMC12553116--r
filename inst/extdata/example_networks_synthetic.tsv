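region	network
A1	Early Auditory
LBelt	Early Auditory
MBelt	Early Auditory
TA2	Auditory Association
STGa	Auditory Association
A5	Auditory Association
PSL	Temporo-Parieto-Occipital Junction
STV	Temporo-Parieto-Occipital Junction
TPOJ1	Temporo-Parieto-Occipital Junction
V1	Early Visual
V2	Early Visual
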