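>DDref77_synthetic synthetic family-typical extended D/D reference
MTVIVTYKTVGELLRELVQEIAPADLEAVEYFTRLLHEAASGNSTDEELKRAMSQLSEDNALRSAVTGSDAKDLFTK
>DPY30 synthetic DPY-30-like consensus
MSDSEKLNQADALIRENIAKMMGKDPAEQILNEMKNIAHQNDPKMAEITRQMHENMNKESGSDHMSPEMAEHFKNQG
>R1D2 synthetic type-I-like consensus
MEEALKAQAESELLRELVQEIAPADPEAVELWTRLLHEAATGNSSDEELKRAMAQLAEDNALRSAVTGSDAKDLMTK
>R2D2 synthetic type-II-like consensus
MTVIVTYKTVGELLRELVQEIAPADLEAVEYFTRLLHEAASGNSTDEELKRAMSQLSEDNALRSAVTGSDAKDLFTK
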