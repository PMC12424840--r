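match_kind,pattern,bin
keyword,kavalactone,kavalactone
keyword,kava lactone,kavalactone
keyword,chalcone,chalcone
keyword,flavokavain,chalcone
keyword,flavon,flavonoid
keyword,flavan,flavonoid
keyword,isoflav,flavonoid
keyword,cinnam,cinnamic acid
keyword,phenylpropano,cinnamic acid
keyword,alkaloid,alkaloid
keyword,piperamide,alkaloid
keyword,terpen,terpene
keyword,benzen,benzenoid
keyword,benzoic,benzenoid
keyword,benzaldehyde,benzenoid
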