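>Dmel_TypeI_BIR
PQHAHNYWENNQHFMQYLWHWFGQYGPAGLGFFGTFDEYTATDYPNVKHMEFPRWECVTCQTTWIWPAWGDEEPDAHQDVAKRCQVGILDSREIVVRFKD
>Dmel_TypeII_BIR
PQHQHNNWENNQHFMQHLWHWFGQYGPAGLGFFGTFDEYVATDYPNVKHMEFPREECVTCQNTWIWDETVDEWPDQHQDHAKRCSVGILDSREIVVRPYG
>Hsap_TypeI_BIR
PQSAHNYWERNQGFMQHLWHWFGQYGPAGLGFFGTFDEYTATDYPNVKHMEFPRWECVTCWNTWIWPATVDECPDAHQDLAKRCSFVTLDSREIPVRPKG
>Hsap_TypeII_BIR
PQHEHKYWGNNQHFMQHLWHWFGWYGPAGLGFFGTCDEYTATDYPNVKHMTFPRWECVTCQNTWIWPATVDECPDQHCDHAKRCSVGILVSREIVVRPKG
>Mmus_TypeI_BIR
PQHAHNYWENNQHFMQLLWHWFGQFGPCGLGFFGTFVEYTATDYPNVFHMEFPHWECVTCQNKWIWPAMVDECPDAHQDVAKRCSVGILDSREIVVRPKG
>Mmus_TypeII_BIR
PQHAHNYWENNDHFMQHLWHWFGQYGPGGLGFEGPFDEYTATIYPNVKHMEFPRWECVTCQNTYIWPATVDECPQEHQDWAKWCSVGILDSREIVVRPKG
>Drer_TypeI_BIR
PQHAHNYCENNQDFMQHLWHWFGQYGPAGLGFFGTSDSYTATDYPNVKHMEFPSWECVTCTNTWIWPATVDECPDAHTDLAKRCSVGILDEREIVVRPKG
>Drer_TypeII_BIR
PQHAHNYWENNQHFMQHLWEWFGQYGPAGLGFFGTFDEYTLTDYPFVKHMEFPRWECVTCQNTLIWPANVDECPDQHWDHAKRCSQDILDSREIVVRPKG
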