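>synthetic_human_prelaminA synthetic stand-in for human prelamin A (not the database sequence): CSIM CAAX terminus, Zmpste24 site 18 residues from the C-terminus, progerin deletion 142-191, surrogate peptides IC/LA/hFP in native tryptic context
MAGRTVLCGTCGQPADKGLEAQSTNVDSLAGHEFWYMITVNQSDRGGKASNTLGEVDQHS
FMWYVALIGESTNDQARGAKTSDLGNVEQAHFMYWLVISGTENDQASGHLARGQSLKTPA
GRVSELKNDTQRKASASGSGADLQENSTGVHAFMYWLIRSVGGSGGGSFGDNLVTRGNAK
TEQRNPTLGSAQSPQNCSIM
>synthetic_mouse_prelaminA synthetic stand-in for mouse prelamin A (not the database sequence): CSIM CAAX terminus, Zmpste24 site 18 residues from the C-terminus, progerin deletion 142-191, surrogate peptides IC/LA/pre-LA/zFP/mFP in native tryptic context
MAGRTVLCGTCGQPADKGLEAQSTNVDSLAGHEFWYMITVNQSDRGGKASNTLGEVDQHS
FMWYVALIGESTNDQARGAKTSDLGNVEQAHFMYWLVISGTENDQASGHLARGQSLKTPA
GRVSELKNDTQRAKAAGGAGADLQENSTGVHAFMYWLIARSVGGSGGGSFGDNLVTRNAK
SYLLGNSSPRSQSSQNCSIM
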