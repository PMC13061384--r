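# Benchmark responses (BMRs) per readout, worm type, day and direction.
# bmr units: percent (incidence readouts: percent of animals; continuous
# readouts: percent change from in-plate solvent control).
# direction: + increased response, - decreased response.
readout,description,is_incidence,worm_type,day,direction,bmr
lethality,% dead,TRUE,adult,7,+,10
lethality,% dead,TRUE,adult,12,+,20
lethality,% dead,TRUE,regenerating,7,+,10
lethality,% dead,TRUE,regenerating,12,+,15
stickiness,% stuck individuals,TRUE,adult,7,+,50
stickiness,% stuck individuals,TRUE,adult,12,+,50
stickiness,% stuck individuals,TRUE,regenerating,7,+,50
stickiness,% stuck individuals,TRUE,regenerating,12,+,50
speed_dark,mean speed in 2nd dark cycle,FALSE,adult,7,+,50
speed_dark,mean speed in 2nd dark cycle,FALSE,adult,7,-,50
speed_dark,mean speed in 2nd dark cycle,FALSE,adult,12,+,40
speed_dark,mean speed in 2nd dark cycle,FALSE,adult,12,-,50
speed_dark,mean speed in 2nd dark cycle,FALSE,regenerating,7,+,35
speed_dark,mean speed in 2nd dark cycle,FALSE,regenerating,7,-,30
speed_dark,mean speed in 2nd dark cycle,FALSE,regenerating,12,+,45
speed_dark,mean speed in 2nd dark cycle,FALSE,regenerating,12,-,45
resting_dark,fraction of time resting in 2nd dark cycle,FALSE,adult,7,+,65
resting_dark,fraction of time resting in 2nd dark cycle,FALSE,adult,7,-,40
resting_dark,fraction of time resting in 2nd dark cycle,FALSE,adult,12,+,45
resting_dark,fraction of time resting in 2nd dark cycle,FALSE,adult,12,-,55
resting_dark,fraction of time resting in 2nd dark cycle,FALSE,regenerating,7,+,35
resting_dark,fraction of time resting in 2nd dark cycle,FALSE,regenerating,7,-,60
resting_dark,fraction of time resting in 2nd dark cycle,FALSE,regenerating,12,+,50
resting_dark,fraction of time resting in 2nd dark cycle,FALSE,regenerating,12,-,55
speed_blue,mean speed in blue cycle,FALSE,adult,7,+,55
speed_blue,mean speed in blue cycle,FALSE,adult,7,-,50
speed_blue,mean speed in blue cycle,FALSE,adult,12,+,45
speed_blue,mean speed in blue cycle,FALSE,adult,12,-,50
speed_blue,mean speed in blue cycle,FALSE,regenerating,7,+,40
speed_blue,mean speed in blue cycle,FALSE,regenerating,7,-,40
speed_blue,mean speed in blue cycle,FALSE,regenerating,12,+,70
speed_blue,mean speed in blue cycle,FALSE,regenerating,12,-,40
resting_blue,fraction of time resting in blue cycle,FALSE,adult,7,+,35
resting_blue,fraction of time resting in blue cycle,FALSE,adult,7,-,30
resting_blue,fraction of time resting in blue cycle,FALSE,adult,12,+,30
resting_blue,fraction of time resting in blue cycle,FALSE,adult,12,-,40
resting_blue,fraction of time resting in blue cycle,FALSE,regenerating,7,+,35
resting_blue,fraction of time resting in blue cycle,FALSE,regenerating,7,-,35
resting_blue,fraction of time resting in blue cycle,FALSE,regenerating,12,+,40
resting_blue,fraction of time resting in blue cycle,FALSE,regenerating,12,-,40
wall_preference,fraction of time in outer region of well,FALSE,adult,7,-,35
wall_preference,fraction of time in outer region of well,FALSE,adult,12,-,25
wall_preference,fraction of time in outer region of well,FALSE,regenerating,7,-,40
wall_preference,fraction of time in outer region of well,FALSE,regenerating,12,-,35
locomotor_bursts,sum of locomotor bursts in phototaxis assay,FALSE,adult,7,+,11
locomotor_bursts,sum of locomotor bursts in phototaxis assay,FALSE,adult,7,-,7
locomotor_bursts,sum of locomotor bursts in phototaxis assay,FALSE,adult,12,+,11
locomotor_bursts,sum of locomotor bursts in phototaxis assay,FALSE,adult,12,-,6
locomotor_bursts,sum of locomotor bursts in phototaxis assay,FALSE,regenerating,7,+,18
locomotor_bursts,sum of locomotor bursts in phototaxis assay,FALSE,regenerating,7,-,11
locomotor_bursts,sum of locomotor bursts in phototaxis assay,FALSE,regenerating,12,+,9
locomotor_bursts,sum of locomotor bursts in phototaxis assay,FALSE,regenerating,12,-,6
phototaxis,blue-cycle speed minus 2nd-minute dark speed,FALSE,adult,7,+,35
phototaxis,blue-cycle speed minus 2nd-minute dark speed,FALSE,adult,7,-,45
phototaxis,blue-cycle speed minus 2nd-minute dark speed,FALSE,adult,12,+,30
phototaxis,blue-cycle speed minus 2nd-minute dark speed,FALSE,adult,12,-,40
phototaxis,blue-cycle speed minus 2nd-minute dark speed,FALSE,regenerating,7,+,30
phototaxis,blue-cycle speed minus 2nd-minute dark speed,FALSE,regenerating,7,-,20
phototaxis,blue-cycle speed minus 2nd-minute dark speed,FALSE,regenerating,12,+,35
phototaxis,blue-cycle speed minus 2nd-minute dark speed,FALSE,regenerating,12,-,35
thermotaxis,fraction of time in cold zone,FALSE,adult,12,-,45
thermotaxis,fraction of time in cold zone,FALSE,regenerating,12,-,40
scrunching,% planarians failing to scrunch under noxious heat,TRUE,adult,12,+,25
scrunching,% planarians failing to scrunch under noxious heat,TRUE,regenerating,12,+,50
noxious_rate,rate of displacement change under noxious heat,FALSE,adult,12,+,35
noxious_rate,rate of displacement change under noxious heat,FALSE,adult,12,-,25
noxious_rate,rate of displacement change under noxious heat,FALSE,regenerating,12,+,35
noxious_rate,rate of displacement change under noxious heat,FALSE,regenerating,12,-,30
noxious_strength,median displacement at end of noxious heat,FALSE,adult,12,+,50
noxious_strength,median displacement at end of noxious heat,FALSE,adult,12,-,65
noxious_strength,median displacement at end of noxious heat,FALSE,regenerating,12,+,50
noxious_strength,median displacement at end of noxious heat,FALSE,regenerating,12,-,65
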