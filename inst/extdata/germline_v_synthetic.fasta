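>IGKV3-20-like|L
EIVLTQSPSSLSASVGDRVTITCRASQSVSSYLAWYQQKPGKAPKLLIYGASSRATGVPSRFSGSGSGTDFTLTISSLEPEDFATYYCQQYGSSP
>IGKV1-39-like|L
EIVLTQAPFSLAASVGDRVTITCRASQSVSSYLAWYQQKPGKSPKLLIYGASSRATGVPDRFSGSGSGTEFTLTISNLEPEDFAVYYCQQYGSSP
>IGKV1-33-like|L
EIVLIQSASSLSATVGDRVTITCRASQSVSSYLAWYQQKSGKAPQLLIYGASSRATGVPSRFTGSGSGTDFSLTIDSLEPEDLATYYCQQYGSSP
>IGKV2-28-like|L
EVVLTQTPSPVSPSVGDRVTITCRASQSVSSYLAWYQQKPGRAPKLVIYGASSRATGAPSRFSGSGSGKDFTLVISSLEPEDFATYYCQQYGSSP
>IGKV4-1-like|L
EIVLTQSPATLSASLGERVTITCRASQSVSSYLAWFQQKPGKASKLLIYGASSRATGVPSKFSGSGAGTDFTLTISSMEPEDFATFYCQQYGSSP
>IGKV3-11-like|L
EIVLTESPSSLTASVGDRVSITCRASQSVSSYLAWYQQRPGKAPKLLVYGASSRATGVPSRFSDSGSGTDYTLTISSLEPDDFATYYCQQYGSSP
>IGHV3-23-like|H
EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSAISGSGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYDR
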