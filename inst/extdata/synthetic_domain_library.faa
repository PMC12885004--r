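>Athila 60
HTYQKGGPNCRTFNNTNECPQMKKQFECPQRQRKDCCHESYECQQSQTELNTGCIDKIPE
>TatI 60
CGMNSVRMFHFRGWTMENAQTCRLKCCNMTFKPATFAYPVHYQYWYPCMCMRKTDGVYLV
>TatII 60
VLKPFGGIHDFQGMQAQEYCVYQHMAHNAMHVMSIEQIMMGNWGWWNDIQDMNEMYMCEV
>TatIII 60
VLELGQCMASGHCIAIEWAALAQGSRRGEEFKVNYSWEDESVICMAKRWTTSIMMCNDER
>Phygy 60
MHDAGTSIHGSDRCGCACVFPLGAEWVDHKAPNQQHEQYMKGADPRRMKIVHWGTPQEAG
>Selgy 60
SDYLRRLDLTVDGCACHWKEIMAINYLHIYYGFIMDQRMKWEMYHELQYMGQIVEDILHY
>Bryco 60
REDFLFLRAPHNVCGSVRIETSEFEDGTDVLKSHSDMACVWYMDIKKMAVYAVLSASYKI
>SIRE 60
ATTAGKRMSWICEKMWAFYYAIYECAHNRRCAWMTTTSPICNACLYNQTKHETYPFCMLM
>Bel-Pao 60
RDFITTKMMDKWSRIMPDTTAYPFWIKGHEYSQICTMHDCLYVHINPTKHGASWYPEYHL
>Tekay 60
EAWDEFYMTMWLSMNRHHMQNMHEDKVFEWGPKFGWKATQAIEGTPHPVTPHGYSCGHWW
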