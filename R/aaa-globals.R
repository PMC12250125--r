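# Package-level constants (loaded before all other files).

RNA_BASES <- c("A", "C", "G", "U")
IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

# admissible pairs for the built-in folder: Watson-Crick + G:U wobble
PAIRABLE <- matrix(FALSE, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
PAIRABLE["A", "U"] <- PAIRABLE["U", "A"] <- TRUE
PAIRABLE["G", "C"] <- PAIRABLE["C", "G"] <- TRUE
PAIRABLE["G", "U"] <- PAIRABLE["U", "G"] <- TRUE
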