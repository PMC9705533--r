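# Synthetic compilation of haemoglobin molar extinction coefficients.
# Representative of standard literature tabulations for human haemoglobin in
# water; NOT a verbatim copy of any published dataset (hence "synthetic").
# Reproduces the qualitative features the analysis relies on: the deoxy-Hb
# shoulder near 760 nm, the isosbestic crossing near 797 nm, and the sign
# change of (eps_hb - eps_hbo2) between 760 and 850 nm.
# Columns: wavelength_nm, eps_hb (deoxy), eps_hbo2 (oxy); units cm^-1 M^-1.
wavelength_nm	eps_hb	eps_hbo2
650	3750	368
660	3227	320
670	2795	294
680	2408	278
690	2052	276
700	1794	290
710	1540	314
720	1326	348
730	1102	390
740	1116	446
750	1405	518
760	1549	586
770	1312	650
780	1075	710
790	894	774
800	762	816
810	718	864
820	693	900
830	679	940
840	684	1000
850	691	1058
860	702	1104
870	714	1136
880	727	1168
890	740	1184
900	762	1198
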