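# Diffuse reflectance of the 15 mm extracerebral-depth head slab,
# synthetic layered-slab Monte Carlo (4e6 photons, seed 2024, 850 nm).
id	sds_mm	detected_fraction	detected_count	reflectance_per_mm2
1	5	0.0712494741853279	458971	0.00113397060092933
2	10	0.0196100541724353	212078	0.000156051852792146
3	15	0.0056409289477789	110654	2.99260575223058e-05
4	20	0.00169330889865139	64214	6.73746203504656e-06
5	25	0.000554681633701483	41187	1.76560647691758e-06
6	30	0.00019666843806533	27770	5.21679234470992e-07
7	35	7.98414980831004e-05	19698	1.8153098691125e-07
8	40	3.41052955793656e-05	13943	6.78503297133275e-08
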