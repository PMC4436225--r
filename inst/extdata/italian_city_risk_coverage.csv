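city,group,period,level,level_name,coverage_area_pct
Turin,inland,day,1,very low,0.4
Turin,inland,day,2,low,27.4
Turin,inland,day,3,moderate,55.0
Turin,inland,day,4,high,14.6
Turin,inland,day,5,very high,2.6
Milan,inland,day,1,very low,1.8
Milan,inland,day,2,low,49.1
Milan,inland,day,3,moderate,39.3
Milan,inland,day,4,high,8.4
Milan,inland,day,5,very high,1.4
Padua,inland,day,1,very low,0.5
Padua,inland,day,2,low,48.7
Padua,inland,day,3,moderate,33.2
Padua,inland,day,4,high,8.2
Padua,inland,day,5,very high,9.4
Bologna,inland,day,1,very low,1.2
Bologna,inland,day,2,low,55.0
Bologna,inland,day,3,moderate,37.0
Bologna,inland,day,4,high,6.5
Bologna,inland,day,5,very high,0.3
Florence,inland,day,1,very low,2.1
Florence,inland,day,2,low,44.3
Florence,inland,day,3,moderate,41.7
Florence,inland,day,4,high,8.7
Florence,inland,day,5,very high,3.2
Rome,inland,day,1,very low,0.2
Rome,inland,day,2,low,8.2
Rome,inland,day,3,moderate,76.9
Rome,inland,day,4,high,10.8
Rome,inland,day,5,very high,3.9
Genoa,coastal,day,1,very low,8.7
Genoa,coastal,day,2,low,81.4
Genoa,coastal,day,3,moderate,3.6
Genoa,coastal,day,4,high,5.8
Genoa,coastal,day,5,very high,0.5
Naples,coastal,day,1,very low,0.7
Naples,coastal,day,2,low,8.0
Naples,coastal,day,3,moderate,56.0
Naples,coastal,day,4,high,20.0
Naples,coastal,day,5,very high,15.3
Bari,coastal,day,1,very low,0.0
Bari,coastal,day,2,low,0.3
Bari,coastal,day,3,moderate,88.9
Bari,coastal,day,4,high,7.6
Bari,coastal,day,5,very high,3.2
Palermo,coastal,day,1,very low,0.2
Palermo,coastal,day,2,low,20.8
Palermo,coastal,day,3,moderate,52.9
Palermo,coastal,day,4,high,17.8
Palermo,coastal,day,5,very high,8.3
Catania,coastal,day,1,very low,0.4
Catania,coastal,day,2,low,4.7
Catania,coastal,day,3,moderate,84.1
Catania,coastal,day,4,high,7.2
Catania,coastal,day,5,very high,3.6
Turin,inland,night,1,very low,15.5
Turin,inland,night,2,low,62.2
Turin,inland,night,3,moderate,11.9
Turin,inland,night,4,high,7.8
Turin,inland,night,5,very high,2.6
Milan,inland,night,1,very low,0.5
Milan,inland,night,2,low,45.8
Milan,inland,night,3,moderate,44.7
Milan,inland,night,4,high,7.7
Milan,inland,night,5,very high,1.3
Padua,inland,night,1,very low,5.5
Padua,inland,night,2,low,63.6
Padua,inland,night,3,moderate,15.0
Padua,inland,night,4,high,7.5
Padua,inland,night,5,very high,8.4
Bologna,inland,night,1,very low,83.1
Bologna,inland,night,2,low,9.5
Bologna,inland,night,3,moderate,6.0
Bologna,inland,night,4,high,0.9
Bologna,inland,night,5,very high,0.5
Florence,inland,night,1,very low,17.3
Florence,inland,night,2,low,68.2
Florence,inland,night,3,moderate,6.4
Florence,inland,night,4,high,5.7
Florence,inland,night,5,very high,2.4
Rome,inland,night,1,very low,0.2
Rome,inland,night,2,low,26.0
Rome,inland,night,3,moderate,59.4
Rome,inland,night,4,high,10.6
Rome,inland,night,5,very high,3.8
Genoa,coastal,night,1,very low,0.1
Genoa,coastal,night,2,low,60.2
Genoa,coastal,night,3,moderate,32.7
Genoa,coastal,night,4,high,6.4
Genoa,coastal,night,5,very high,0.6
Naples,coastal,night,1,very low,0.3
Naples,coastal,night,2,low,2.8
Naples,coastal,night,3,moderate,60.3
Naples,coastal,night,4,high,20.9
Naples,coastal,night,5,very high,15.7
Bari,coastal,night,1,very low,10.8
Bari,coastal,night,2,low,79.1
Bari,coastal,night,3,moderate,6.2
Bari,coastal,night,4,high,3.8
Bari,coastal,night,5,very high,0.1
Palermo,coastal,night,1,very low,0.1
Palermo,coastal,night,2,low,65.2
Palermo,coastal,night,3,moderate,10.5
Palermo,coastal,night,4,high,15.8
Palermo,coastal,night,5,very high,8.4
Catania,coastal,night,1,very low,0.2
Catania,coastal,night,2,low,4.0
Catania,coastal,night,3,moderate,83.5
Catania,coastal,night,4,high,8.0
Catania,coastal,night,5,very high,4.3
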