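>fam001_spB
DSLSKRFYMTNSVSAVLAVVVCSHFPSIFRALQASVIASHTCQRQRRPTGCNGAAKSAQL
RLNELSLHSRLMDRVIRDPESLLDIYSKRLDIHPRWCKPPDVFKHSHTKELYQLRTTLRQ
YSAPRSLIVRQLVRPRVLATQSSARAKCGR
>fam002_spB
AALEQGSSFADLVVTGLTDYTDERYPCMWVQRARFIQTSPAGSHRYLTCKLCLVVHCTCV
TLPKRVWRLVVLSLKNGLLLGKPYTLPNLAIYVWCAVHEGQEKTGSGRPLFRSAADTCLG
SGNSVAWHARPLLCVVVSMADPILRSALRI
>fam003_spB
SRRPPGKLYSFRLSTHSRCQPLNWRAMVVLTYYIRPTLLVSIFALVARKVIPVGAIMVPR
SAFTRKKRPTMSGQAAIGYSKLTFKSGLILMKSEGASTRAILDVILARSLLRNSVRSRYG
LRGNVISSFDGVGEPSCASASLLSFIGEYF
>fam004_spB
RQQAFCREKGRCRLYASKVDIRWLKGNSSPGWGGIAFWATMVVYQRPWLQVADHVRYRVV
SRSPQRKTPPAHGRRYRLPICTKRPVKASSLEKCSPSIPGSLYSHLSIHNWSANLSRISP
ELRMSIYCQQNLPRVHYGLEQRERKKPNER
>fam005_spB
RLLKVLSVSATPGPPRDSFLLLSVSSRRGHSVLLESVKGWPVDVKVKAYSNRLANLHTGR
VTTSAQAAVFRLHQIHLILQQYLVAAPISALCTAPGPSRLTDDRLPSHTSPYGGVHFLLV
GYTRGHRLPKLLDCATAFSSITSPRNRRRV
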