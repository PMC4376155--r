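handle,state,group
@HealthCareGov,US,federal
@CoveredCA,CA,state
@C4HCO,CO,state
@AccessHealthCT,CT,state
@DCHealthLink,DC,state
@HIHealthConnect,HI,state
@YourHealthIdaho,ID,state
@kynectky,KY,state
@MarylandConnect,MD,state
@HealthConnector,MA,state
@MNsure,MN,state
@NVHealthLink,NV,state
@NMHIX,NM,state
@NYStateofHealth,NY,state
@CoverOregon,OR,state
@HealthSourceRI,RI,state
@VTHealthConnect,VT,state
@WAPlanfinder,WA,state
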