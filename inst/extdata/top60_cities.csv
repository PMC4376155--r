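city,state,rank
New York,NY,1
Los Angeles,CA,2
Chicago,IL,3
Houston,TX,4
Philadelphia,PA,5
Phoenix,AZ,6
San Antonio,TX,7
San Diego,CA,8
Dallas,TX,9
San Jose,CA,10
Austin,TX,11
Jacksonville,FL,12
Indianapolis,IN,13
San Francisco,CA,14
Columbus,OH,15
Fort Worth,TX,16
Charlotte,NC,17
Detroit,MI,18
El Paso,TX,19
Memphis,TN,20
Boston,MA,21
Seattle,WA,22
Denver,CO,23
Washington,DC,24
Nashville,TN,25
Baltimore,MD,26
Louisville,KY,27
Portland,OR,28
Oklahoma City,OK,29
Milwaukee,WI,30
Las Vegas,NV,31
Albuquerque,NM,32
Tucson,AZ,33
Fresno,CA,34
Sacramento,CA,35
Long Beach,CA,36
Kansas City,MO,37
Mesa,AZ,38
Virginia Beach,VA,39
Atlanta,GA,40
Colorado Springs,CO,41
Omaha,NE,42
Raleigh,NC,43
Miami,FL,44
Oakland,CA,45
Minneapolis,MN,46
Tulsa,OK,47
Cleveland,OH,48
Wichita,KS,49
Arlington,TX,50
New Orleans,LA,51
Bakersfield,CA,52
Tampa,FL,53
Honolulu,HI,54
Aurora,CO,55
Anaheim,CA,56
Santa Ana,CA,57
St. Louis,MO,58
Riverside,CA,59
Corpus Christi,TX,60
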