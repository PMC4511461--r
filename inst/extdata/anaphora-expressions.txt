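the bacterium
this bacterium
the organism
this organism
the species
this species
the genus
this genus
this group of organisms
the bacteria
these bacteria
these organisms
these species
this microorganism
the microorganism
these microorganisms
this microbe
the microbe
these microbes
this bacterial species
the bacterial species
this bacterial strain
this strain of bacteria
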