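# Reduced discrete-time absorption rate k_red(s') = k*dt/sigma_b^3 of an
# absorbing unit sphere under Gaussian steps with 1-D rms s' (mutual
# diffusion), computed by the radial propagator solver (.reducedRate).
# Regenerate with: vox4d:::.writeReducedRateTable()
s_reduced	k_reduced
0.05	0.0151472732
0.05860511488	0.0207233095
0.06869118979	0.02833484203
0.08051310138	0.03870042512
0.09436959111	0.05277430053
0.1106108146	0.0718194342
0.1296471899	0.09750868811
0.1519597691	0.1320687799
0.1781123945	0.1783792024
0.2087659468	0.2401486444
0.2446950459	0.3219832308
0.2868076255	0.429500163
0.3361678768	0.5694631327
0.3940231408	0.7494416618
0.4618354286	0.9765148992
0.5413183669	1.256863085
0.6344805016	1.590600061
0.7436760536	1.969119612
0.8716644111	2.371950392
1.021679859	2.769034549
1.19751331	3.129184036
1.403608102	3.430157018
1.645172281	3.663865737
1.928310211	3.834622482
2.260176828	3.953617446
2.649158453	4.033689823
3.105084709	4.086241733
3.639476922	4.120137588
4.265839262	4.14174124
5	4.155400264
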