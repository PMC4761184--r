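CNO	met001
C(C(=N)O)O	met002
C(CO)CO	met003
C=CC=CN	met004
CC(C=C)N	met005
CN(C=C)O	met006
C(=C(N)N=N)N	met007
C(=CC(N)=N)N	met008
C(=N)=NC=C=N	met009
C(C(=N)NO)O	met010
C(C(N=O)O)=O	met011
C(C=NO)=NO	met012
C(N)N(C=O)O	met013
C(N)OC(N)=O	met014
C=C(O)OC=N	met015
C=C=C(C)ON	met016
C=CC(C)=C=O	met017
C=CC(CO)=O	met018
CC(=N)NC=O	met019
CC(C(C)=O)O	met020
CC=CN=C=C	met021
CN=CN=CC	met022
CNC(C)=CC	met023
CNC(CO)=O	met024
CNC(N=C)O	met025
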