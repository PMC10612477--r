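>fam001_spC
DSLSKRFYMTNSVSAVLAGVVCSHFPRIFRPLQTGVIASHAFQRQRRPTGCNGAVKSAQL
RLNELSQHSRLMDRVIRDPESLLDIYSKRLDIHPRRCKPPEVFKHSHTKELYQLRTTLWQ
YSAPRSLIVRQLVRPRVLATQSSARAKCGL
>fam002_spC
AALQQGTSVADLVVTGLTDYTDERYPCMWIQRARSIQTSPAGSHRYLTCKLCLVVHCTCV
TLPKHVWKLVVLSLKNGLLLGKPYTLRNLAIYVRCAVPEGQEKTGYGRPLCRSAADTCLG
SEKSDDWHARPLLYVVVSMADPILRSALRI
>fam003_spC
SRRTTGKLYSFRLSTHSRCQPLNWRAMVVLTYYVRPTLPASISALVARKVIPVGAIMVPR
SAFTRKRRPTISGQAAIGYSQLTFKSGLILMKSEGASTRAILEVILARSLLRNSVRSRYR
LRGNVISSFDGVGEPSCASASLLSFIGEYF
>fam004_spC
WQQAFCREKCSCRLYASKVDIRWLKGYSSRGSGGIAFWATMLVYERPWLQVADHVRYRVV
SRSTQRKTPPAHGRRYRVPICTKRPVKAPSLEKCSPSIPGSLYSHPSIDNWSANLSRISP
ELRMFIYCQQNLPRVQYGLEQRERKRPNER
>fam005_spC
RLLKVLSASWIPGPPRDSFLHLSVSSKPGHTVLLESVKDWPVDDKVTAYSSRLADLNTSR
VTTSAQVVIFRLHYIHVILQQYLVAAPISAIRTALGPSRLTVDRLPSYTITYGGVHFLLV
TYTRGHHLPKFLDCATAFSSINSFRTRRQV
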