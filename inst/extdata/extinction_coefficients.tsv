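# Molar extinction coefficients of oxy- and deoxyhemoglobin, base-10,
# units cm^-1 mM^-1, compiled from the Prahl/OMLC literature tabulation
# (S. Prahl, "Optical absorption of hemoglobin", Oregon Medical Laser
# Center) after division by 1000 from cm^-1 M^-1.
# version: 1
wavelength_nm	eps_hbo2	eps_hbr
690	0.2760	2.0520
730	0.3900	1.1022
760	0.5860	1.5485
780	0.7100	1.0754
800	0.8160	0.7617
830	0.9740	0.6930
850	1.0580	0.6913
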