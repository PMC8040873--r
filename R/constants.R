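# Physical constants used throughout. Energies are kcal mol^-1 and
# entropies cal K^-1 mol^-1 to match the conventional calorimetry units.
.R_KCAL <- 1.9872e-3     # gas constant, kcal mol^-1 K^-1
.KB_J <- 1.380649e-23    # Boltzmann constant, J K^-1
.H_J <- 6.62607015e-34   # Planck constant, J s

# Element classes used for pocket-occupancy annotation. Uranyl (U) is
# treated as a divalent cation moiety.
.DIVALENT_ELEMENTS <- c("MG", "CA", "MN", "ZN", "FE", "NI", "CO", "CU",
                        "CD", "SR", "BA", "U")
.MONOVALENT_ELEMENTS <- c("NA", "K", "LI", "RB", "CS")
.ION_ELEMENTS <- c(.DIVALENT_ELEMENTS, .MONOVALENT_ELEMENTS)
.WATER_RESIDUES <- c("HOH", "WAT", "H2O", "DOD")
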