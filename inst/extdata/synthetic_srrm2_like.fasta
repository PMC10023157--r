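>SYN_SRRM2_LIKE synthetic stand-in sequence; planted RS runs tiling to 56 4-mer units
YEMNTLDMHFEYIPMKLTNNIWYAMPEAKMCCEYIVVTDDSRPHCMTCKFHENWEACELT
DRSRYNLNWYGKVQEHSRSRGFFDMEWMCMAAVSRSRSEPGHNPVEEMIARSRSDDGCSR
METPLRSRSRDYWHITKNKADQYFSRSRIYDWCAKLNVNGTPGQSRSRSRCKHYQFCVNE
MLLCNSRSFMFKYQSRSRSRTYPMHIQPKDSRSRKDDNKRSRSRSTDVFALGESRSRSRS
RIEMNCTVGSRSRSRSRANNKQETKQHMMKGEFSRSRLNADTYNVELHWMWQVKFYQSRS
RSNNWCDKVKLYNEHTPWMFFLRSRSRWPYNNLTMFAENERSTDMVCMFKIHDYTPEYVW
RSRSRSRSRSCCGAANEWEWHNKAQKIMQSRSWPNYKLMNENCGHIQAWSRSRKWHFCED
LSRGCETEPDGQWSRSRSRSRSRSRSRSRYHYKVINDCQCEKHKTVRSRSRSRSRSRSYI
LQFYHCQMNHSRSRSRYNFFFCWGTECWHVFDTTCSRSRSKKQPCEAWCTCDQALCESRS
RSINADEGVYVAAIKTHRSRLKVVFWQSRSRVNIWVSRSRSRSRQFKMEMEVPHPFIVFL
ILSRSRSRSRSRSRSRSREHAAPAPELSRSRSRSRSRSRSRSRTGTHANEAMGKKTDMSR
SRSLTKQQGYYSRSRELNLPKEFFNATVDYLFARSRSWPKPEAERSRSRSTQKVCMWFNI
ECAMSRPWCGYFHQMVLPKGRSRSRHCCDEIQTKDVWYNNSRSRYPEKDKPKEQATDLSR
DYLKFAKVINWLSRSRSRSRSRQEKDYPWKYWYKCLRSMIAIAPRSRMWHKIPLLSRATT
NRSRSRSRSGPIGVAQAQTHEFKPELRSGYCHCPFENWEWIAPYQSRSRSRSRSRTAKCF
NCFIFQTKAAIGFEASRKHDNLLKFDFGWTKKHKKGRSCYELGIHYTDQWQGMSRSHNLI
GKGRSRSRSKDKCMVAGMLNIRSILQEKVPIAKYHRSRSRSRSRSRSVECKLGEVAEVLI
YPDGEKFKPHPDMQPAINYPHVQDPVVMNAQFAFWAGQNKVEWWLV
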