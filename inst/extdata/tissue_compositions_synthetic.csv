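# SYNTHETIC representative mammalian tissue compositions (mass fractions).
# These are order-of-magnitude illustrative values assembled for examples and
# tests, NOT a transcription of any published composition table: for
# quantitative organ/milk predictions substitute compositions from the
# toxicokinetic literature for your species of interest.
# Basis: mass fractions; partition coefficients applied on a matching basis.
# For cow_milk the aqueous fraction lumps dissolved lactose and minerals
# into the water phase.
tissue,f_water,f_storage_lipid,f_phospholipid,f_structural_protein,f_albumin
plasma,0.9451,0.0023,0.0016,0.016,0.035
blood,0.8195,0.0023,0.0032,0.145,0.03
muscle,0.762,0.02,0.008,0.205,0.005
liver,0.713,0.045,0.027,0.205,0.01
kidney,0.773,0.025,0.022,0.17,0.01
brain,0.775,0.04,0.055,0.125,0.005
adipose,0.145,0.79,0.012,0.05,0.003
lung,0.793,0.015,0.012,0.17,0.01
heart,0.736,0.055,0.021,0.18,0.008
skin,0.657,0.06,0.008,0.27,0.005
cow_milk,0.9275,0.039,0.0008,0.0265,0.0062
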