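>fam001_spA
DSLRKRLYMTNSVTTVLAGVVCSHFPKTFRALETGVIASHAFQRQRRLTGCNGAVKSAQL
RLNELSLHSRLMDCVIRDPESLLDIYSKRLDVHPRWCKPPDVFKHSHTKELYQLRTTLRQ
YWVPRSLIVRQLVRPRVLATQSSARAKCGL
>fam002_spA
AALQQGTSFADLVVTGLTDNTDERYPCMWVHRARIIQTSPAGSHRYLTCKLCLVVHCTCV
TLPKRVWKLVVLSLKNGLLLGKPYTLPNFAIYVWCAVPEGQEKTGFGRPLFRSAADTCLG
SGNSDDWHARPPLYVVVSMADPILRSALRI
>fam003_spA
SRRTPGKLYSFRLSTHSRCQPLNWRAMVVLTYYVRPTLLASISALVARKVIPVGAIMVPR
SAFARKKRPTMSGQAAIGYSKLTIKSGLILMNSEGASTRAILDVILARSLLSNSVRSRYR
LRGNVISSFDGVGEPSCASASLLSFIGEYF
>fam004_spA
RQQAFCRGKRRGRFYAFKVDIRWLKGNSSTGSGGIAFWATMLVYERPWLQVTDHIRYGVV
SRSPQRKTPPAHGRRYRLPICTKKPVKAPSLEKCSPSIPGSLYSHRGIDNWSANLSRISP
ELRMSIYCQQNLPRVHYGLEQRERKEPNER
>fam005_spA
RLLKVLSVSASPGPPRNSFLQLSVSSRPGHSVPLDSVKVWPVADKVKAYSSRLAFLSTSR
VATSAQVAVFRLHVIHLLLQQYLVAAPISAIRTALGPSRLTADRLSSYTSPYGGVHFLLV
TCTRGHRLPYLLDYATAFSSITSVRARRQV
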