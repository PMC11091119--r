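elev_class,forest_type,aspect_class,ex_m,en_m,he_m
<550,deciduous_broadleaf,sunny,407.51,67.92,17.56
<550,deciduous_broadleaf,shady,438.58,53.15,8.19
<550,temperate_conifer,sunny,378.51,79.12,24.22
<550,temperate_conifer,shady,404.91,64.89,16.46
<550,mixed,sunny,370.57,83.01,26.26
<550,mixed,shady,399.43,70.13,10.46
550-900,deciduous_broadleaf,sunny,700.89,110.01,34.51
550-900,deciduous_broadleaf,shady,700.58,108.92,34.73
550-900,temperate_conifer,sunny,695.54,124.66,48.07
550-900,temperate_conifer,shady,706.86,116.89,40.92
550-900,mixed,sunny,701.82,122.30,46.43
550-900,mixed,shady,686.65,109.73,33.66
900-1100,deciduous_broadleaf,sunny,963.56,46.08,12.13
900-1100,deciduous_broadleaf,shady,965.84,57.76,17.90
900-1100,temperate_conifer,sunny,987.51,60.86,21.50
900-1100,temperate_conifer,shady,983.87,57.78,19.57
900-1100,mixed,sunny,992.33,56.72,19.61
900-1100,mixed,shady,988.66,57.10,20.46
1100-1350,temperate_conifer,sunny,1182.76,57.93,18.60
1100-1350,temperate_conifer,shady,1188.50,59.57,21.50
1100-1350,mixed,sunny,1213.16,64.36,21.73
1100-1350,mixed,shady,1218.48,61.54,17.06
>=1350,temperate_conifer,sunny,1377.64,64.09,26.90
>=1350,temperate_conifer,shady,1382.60,59.60,21.02
>=1350,mixed,sunny,1373.57,48.58,16.77
>=1350,mixed,shady,1389.07,56.38,16.27
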