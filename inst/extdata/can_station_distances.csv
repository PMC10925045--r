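station_id,distance_km
1351A,28.61
1352A,32.11
1353A,33.45
1354A,34.19
1355A,49.33
1356A,9.68
1357A,29.05
1358A,27.20
1359A,26.45
1360A,16.71
1376A,46.45
1377A,43.28
1378A,41.92
1719A,43.10
1720A,46.19
1721A,36.46
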