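>ROPN1_Nterm_synthetic synthetic stand-in N-terminal region
MTVIVTYKTVGVLLRELVQPIAPADLEAVEYFTRLLHEAASGESTDEELKRAMSQLSEDNALRSAVTGSDAKDLFTK
>ROPN1L_Nterm_synthetic synthetic stand-in N-terminal region
MTDIVTYKWVGELLRELVQEIAPADLEAVEYFTRSLHEYASGNDTDEELKRAMSQLHEDNALRSAVTGSDAKDLFTK
>SPA17_Nterm_synthetic synthetic stand-in N-terminal region
MTVIVTYKTVGELLRELVQEIAPADLEAVEYFTRLLHEAASFNSTDEELKRAMSQLSEDNALRSAVQGSDAKDTFTK
>RIIAD1_Nterm_synthetic synthetic stand-in N-terminal region
MTVIVTYKTVGELLRELVQEIAPADLEAKEYFTRLLHEAASGNSTQEELKRAMSQLSEDNQLRYADTGSDAKDLFTK
>CATIP_Nterm_synthetic synthetic stand-in N-terminal region
RAVIVTYKTVGELLSELVQEIAPAVLEAVEYFTRLLPECASGNSTDEELKRARSQLSEDNALRSAVTGSDAKDLFTK
>ROPN1B_Nterm_synthetic synthetic stand-in N-terminal region
MEEALKAQAESELHRELVQEIAPADPEAVIKWTALLHENATGNSSDEELKRAMFQLAEDNALRSAHTGSYAKDLMTK
>CABYR_Nterm_synthetic synthetic stand-in N-terminal region
MEEHLKAQAESELLRELVQEPAPADPETTELWTRLLHEAATGNSSDEELKRAMAQLAEDNALRSAVTGSDAKDLMTK
>PRKAR2A_Nterm_synthetic synthetic stand-in N-terminal region
MENALRAQAESELLLELVQTIAPADPEAVELITGLLHEAATGASSDEELKRAMAQAAEDNALRCAVTGSDAKDLMTK
>PRKAR2B_Nterm_synthetic synthetic stand-in N-terminal region
MKLALKAQAESELLRELVQEIAPADPEAVELHTRLLHEAATGNSSDEELKRAMAQLEEDNALRSAVTGSDAKDLMTK
>TPGS1_Nterm_synthetic synthetic stand-in N-terminal region
MEEALKAQAESELLRELVQEIAPADPEAVELWTRLYHEAATGNSTDEELKRAMAQTAEDNVDRFAVTGSDAKDLMHK
>PRKAR1A_Nterm_synthetic synthetic stand-in N-terminal region
MEEALKANAPSELLRELVQESAPADPEAVELWTRLLHSAATGNSSDEELKRAFAWLAEDNALVSAVTGSDAKDLMTK
>PRKAR1B_Nterm_synthetic synthetic stand-in N-terminal region
MEEALKAQAESELLRELNQEIAPMDPEAGELWTRLLHEAATGNSSDEELKRAMAQLNEDNALRSAVTGSDAKDLYTK
>VEST1_Nterm_synthetic synthetic stand-in N-terminal region
MEEALKAQAESELLRELVQEIGPWDPEAVELYTRLLAEAATGNSSDEELKRAMRQLAEDNALRSAVTGSDAKDLMTK
>AK8_Nterm_synthetic synthetic stand-in N-terminal region
MEEALKAEAESELLRELVQEIAPADPEAVEQWIRPLEEAATGNSSDKKLKRAMAQLAEDNALRSAITGSDAKDAMTK
>AK5_Nterm_synthetic synthetic stand-in N-terminal region
MEEALAAQAELELLRELVQEIAPADPEAVILWTRLLKEAATGNSSDEELKRAMAQLAEDNALRHYVTGSDAKDLMTK
>FBXL13_Nterm_synthetic synthetic stand-in N-terminal region
MEEALKAQAYSELLRELVQEIAPADPEAVELWTRLLIGAATGNSSDEELKRAMAQGAEDNTERSAVTRSDAKMLMTK
>TEX55_Nterm_synthetic synthetic stand-in N-terminal region
MDEALKAQAESELLVELVQEDAPADPEAVELGTRLQHECATMDSSDSELKRAMAQLAEDNALRSAVTASDAKDLMTK
>EFCAB10_Nterm_synthetic synthetic stand-in N-terminal region
MEEALKAWAESELLRELVQELAPADPEAVELWTRLLHEAATGNSSSEKLKRAMAILAEDNALRSAVTGSEAKDLMTK
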