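species,trait,acclimation_temp,experimental_temp,mean,ci_low,ci_high,n
J. edwardsii,smr,14,21.5,44.3,38.1,50.5,6
J. edwardsii,smr,21.5,21.5,29.0,21.4,36.5,6
S. verreauxi,smr,14,21.5,45.9,33.4,58.3,6
S. verreauxi,smr,21.5,21.5,30.0,25.8,34.2,6
J. edwardsii,epoc,14,NA,375.6,311.1,440.1,18
J. edwardsii,epoc,21.5,NA,156.7,109.9,203.6,18
S. verreauxi,epoc,14,NA,398.4,291.7,505.1,18
S. verreauxi,epoc,21.5,NA,238.3,155.5,321.0,18
J. edwardsii,recovery_time,14,NA,12.0,10.1,14.0,18
J. edwardsii,recovery_time,21.5,NA,7.3,5.2,9.4,18
S. verreauxi,recovery_time,14,NA,12.4,9.7,15.1,18
S. verreauxi,recovery_time,21.5,NA,7.4,5.4,9.4,18
J. edwardsii,recovery_rate,14,NA,32.4,28.1,36.8,18
J. edwardsii,recovery_rate,21.5,NA,22.0,18.3,25.7,18
J. edwardsii,aerobic_scope,NA,NA,75.6,70.3,81.0,54
S. verreauxi,aerobic_scope,NA,NA,89.2,83.3,94.6,54
J. edwardsii,mmr,NA,NA,101.7,96.1,107.2,54
S. verreauxi,mmr,NA,NA,114.6,108.5,120.6,54
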