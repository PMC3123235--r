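LOCUS       NC_012920              16569 bp    DNA     circular PRI 01-JAN-2011
DEFINITION  Homo sapiens mitochondrion, complete genome (rCRS).
ACCESSION   NC_012920
COMMENT     Feature-table-only extract of the public revised Cambridge
            Reference Sequence annotation (canonical gene, rRNA, tRNA and
            D-loop coordinates); the sequence block is omitted.
FEATURES             Location/Qualifiers
     source          1..16569
                     /organism="Homo sapiens"
                     /organelle="mitochondrion"
     D-loop          join(16024..16569,1..576)
                     /note="control region"
     gene            577..647
                     /gene="TRNF"
     tRNA            577..647
                     /gene="TRNF"
     gene            648..1601
                     /gene="RNR1"
     rRNA            648..1601
                     /gene="RNR1"
     gene            1602..1670
                     /gene="TRNV"
     tRNA            1602..1670
                     /gene="TRNV"
     gene            1671..3229
                     /gene="RNR2"
     rRNA            1671..3229
                     /gene="RNR2"
     gene            3230..3304
                     /gene="TRNL1"
     tRNA            3230..3304
                     /gene="TRNL1"
     gene            3307..4262
                     /gene="ND1"
     CDS             3307..4262
                     /gene="ND1"
                     /codon_start=1
     gene            4263..4331
                     /gene="TRNI"
     tRNA            4263..4331
                     /gene="TRNI"
     gene            complement(4329..4400)
                     /gene="TRNQ"
     tRNA            complement(4329..4400)
                     /gene="TRNQ"
     gene            4402..4469
                     /gene="TRNM"
     tRNA            4402..4469
                     /gene="TRNM"
     gene            4470..5511
                     /gene="ND2"
     CDS             4470..5511
                     /gene="ND2"
                     /codon_start=1
     gene            5512..5579
                     /gene="TRNW"
     tRNA            5512..5579
                     /gene="TRNW"
     gene            complement(5587..5655)
                     /gene="TRNA"
     tRNA            complement(5587..5655)
                     /gene="TRNA"
     gene            complement(5657..5729)
                     /gene="TRNN"
     tRNA            complement(5657..5729)
                     /gene="TRNN"
     gene            complement(5761..5826)
                     /gene="TRNC"
     tRNA            complement(5761..5826)
                     /gene="TRNC"
     gene            complement(5826..5891)
                     /gene="TRNY"
     tRNA            complement(5826..5891)
                     /gene="TRNY"
     gene            5904..7445
                     /gene="COX1"
     CDS             5904..7445
                     /gene="COX1"
                     /codon_start=1
     gene            complement(7446..7514)
                     /gene="TRNS1"
     tRNA            complement(7446..7514)
                     /gene="TRNS1"
     gene            7518..7585
                     /gene="TRND"
     tRNA            7518..7585
                     /gene="TRND"
     gene            7586..8269
                     /gene="COX2"
     CDS             7586..8269
                     /gene="COX2"
                     /codon_start=1
     gene            8295..8364
                     /gene="TRNK"
     tRNA            8295..8364
                     /gene="TRNK"
     gene            8366..8572
                     /gene="ATP8"
     CDS             8366..8572
                     /gene="ATP8"
                     /codon_start=1
     gene            8527..9207
                     /gene="ATP6"
     CDS             8527..9207
                     /gene="ATP6"
                     /codon_start=1
     gene            9207..9990
                     /gene="COX3"
     CDS             9207..9990
                     /gene="COX3"
                     /codon_start=1
     gene            9991..10058
                     /gene="TRNG"
     tRNA            9991..10058
                     /gene="TRNG"
     gene            10059..10404
                     /gene="ND3"
     CDS             10059..10404
                     /gene="ND3"
                     /codon_start=1
     gene            10405..10469
                     /gene="TRNR"
     tRNA            10405..10469
                     /gene="TRNR"
     gene            10470..10766
                     /gene="ND4L"
     CDS             10470..10766
                     /gene="ND4L"
                     /codon_start=1
     gene            10760..12137
                     /gene="ND4"
     CDS             10760..12137
                     /gene="ND4"
                     /codon_start=1
     gene            12138..12206
                     /gene="TRNH"
     tRNA            12138..12206
                     /gene="TRNH"
     gene            12207..12265
                     /gene="TRNS2"
     tRNA            12207..12265
                     /gene="TRNS2"
     gene            12266..12336
                     /gene="TRNL2"
     tRNA            12266..12336
                     /gene="TRNL2"
     gene            12337..14148
                     /gene="ND5"
     CDS             12337..14148
                     /gene="ND5"
                     /codon_start=1
     gene            complement(14149..14673)
                     /gene="ND6"
     CDS             complement(14149..14673)
                     /gene="ND6"
                     /codon_start=1
     gene            complement(14674..14742)
                     /gene="TRNE"
     tRNA            complement(14674..14742)
                     /gene="TRNE"
     gene            14747..15887
                     /gene="CYTB"
     CDS             14747..15887
                     /gene="CYTB"
                     /codon_start=1
     gene            15888..15953
                     /gene="TRNT"
     tRNA            15888..15953
                     /gene="TRNT"
     gene            complement(15956..16023)
                     /gene="TRNP"
     tRNA            complement(15956..16023)
                     /gene="TRNP"
//
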