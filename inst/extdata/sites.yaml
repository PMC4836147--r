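# The four monitored sites in the central Ecuadorian province of Cotopaxi.
# mean_annual_temp / intra_annual_sd are the 50-year monthly climatology
# statistics (deg C); field areas in m2.
Lowland 1:
  local_name: La Hoya
  elevation: 2713
  n_fields: 40
  mean_annual_temp: 13.3
  intra_annual_sd: 0.58
  mean_field_area: 4198
  sd_field_area: 5376
  mean_monthly_abundance: 139
Lowland 2:
  local_name: Anchilivi
  elevation: 2727
  n_fields: 84
  mean_annual_temp: 13.71
  intra_annual_sd: 0.63
  mean_field_area: 1937
  sd_field_area: 1177
  mean_monthly_abundance: 134
Highland 1:
  local_name: Palama Medio
  elevation: 3280
  n_fields: 74
  mean_annual_temp: 10.1
  intra_annual_sd: 0.52
  mean_field_area: 2999
  sd_field_area: 1794
  mean_monthly_abundance: 86
Highland 2:
  local_name: Palama Bajo
  elevation: 3152
  n_fields: 58
  mean_annual_temp: 10.81
  intra_annual_sd: 0.55
  mean_field_area: 3104
  sd_field_area: 2383
  mean_monthly_abundance: 99
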