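>CASB_BOVIN name=beta-casein signal_length=15 source_accession=UniProt:P02666|A2|mature
RELEELNVPGEIVESLSSSEESITRINKKIEKFQSEEQQQTEDELQDKIHPFAQTQSLVY
PFPGPIPNSLPQNIPPLTQTPVVVPPFLQPEVMGVSKVKEAMAPKHKEMPFPKYPVEPFT
ESQSLTLTDVENLHLPLPLLQSWMHQPHQPLPPTVMFPPQSVLSLSQSKVLPVPQKAVPY
PQRDMPIQAFLLYQEPVLGPVRGPFPIIV
>CASA1_BOVIN name=alpha-s1-casein signal_length=15 source_accession=UniProt:P02662|B|mature
RPKHPIKHQGLPQEVLNENLLRFFVAPFPEVFGKEKVNELSKDIGSESTEDQAMEDIKQM
EAESISSSEEIVPNSVEQKHIQKEDVPSERYLGYLEQLLRLKKYKVPQLEIVPNSAEERL
HSMKEGIHAQQKEPMIGVNQELAYFYPELFRQFYQLDAYPSGAWYYVPLGTQYTDAPSFS
DIPNPIGSENSEKTTMPLW
>CASA2_BOVIN name=alpha-s2-casein signal_length=15 source_accession=UniProt:P02663|A|mature
KNTMEHVSSSEESIISQETYKQEKNMAINPSKENLCSTFCKEVVRNANEEEYSIGSSSEE
SAEVATEEVKITVDDKHYQKALNEINQFYQKFPQYLQYLYQGPIVLNPWDQVKRNAVPIT
PTLNREQLSTSEENSKKTVDMESTEVFTKKTKLTEEEKNRLNFLKKISQRYQKFALPQYL
KTVYQHQKAMKPWIQPKTKVIPYVRYL
>CASK_BOVIN name=kappa-casein signal_length=21 source_accession=UniProt:P02668|A|mature
QEQNQEQPIRCEKDERFFSDKIAKYIPIQYVLSRYPSYGLNYYQQKPVALINNQFLPYPY
YAKPAAVRSPAQILQWQVLSNTVPAKSCQAQPTTMARHPHPHLSFMAIPPKKNQDKTEIP
TINTIASGEPTSTPTTEAVESTVATLEDSPEVIESPPEINTVQVTSTAV
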