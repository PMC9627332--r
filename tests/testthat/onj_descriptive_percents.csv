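ingredient,variable,category,percent
zoledronic acid,sex,F,54.49
zoledronic acid,sex,M,39.07
zoledronic acid,sex,Unknown,6.44
zoledronic acid,continent,Unknown,2.92
zoledronic acid,continent,NorthAmerica,19.28
zoledronic acid,continent,Oceania,0.77
zoledronic acid,continent,Africa,0.29
zoledronic acid,continent,SouthAmerica,2.34
zoledronic acid,continent,Europe,51.23
zoledronic acid,continent,Asia,23.17
zoledronic acid,reporter_group,Unknown,6.93
zoledronic acid,reporter_group,Physician,19.4
zoledronic acid,reporter_group,OtherHealthProfessional,58.75
zoledronic acid,reporter_group,Consumer,12.33
zoledronic acid,reporter_group,Pharmacist,1.76
zoledronic acid,reporter_group,Lawyer,0.83
zoledronic acid,indication_group,CancerRelated,90.02
zoledronic acid,indication_group,OsteoporosisRelated,9.98
zoledronic acid,outcome,DE,6.58
zoledronic acid,outcome,DS,7.25
zoledronic acid,outcome,HO,17.23
zoledronic acid,outcome,LT,0.58
zoledronic acid,outcome,OT,68.36
alendronate,sex,F,80.42
alendronate,sex,M,9.89
alendronate,sex,Unknown,9.69
alendronate,continent,Unknown,0.44
alendronate,continent,NorthAmerica,59.89
alendronate,continent,Oceania,0.12
alendronate,continent,Africa,0
alendronate,continent,SouthAmerica,0.24
alendronate,continent,Europe,33.04
alendronate,continent,Asia,6.27
alendronate,reporter_group,Unknown,7.31
alendronate,reporter_group,Physician,32.33
alendronate,reporter_group,OtherHealthProfessional,37.89
alendronate,reporter_group,Consumer,16.76
alendronate,reporter_group,Pharmacist,1.43
alendronate,reporter_group,Lawyer,4.29
alendronate,indication_group,CancerRelated,1.83
alendronate,indication_group,OsteoporosisRelated,98.17
alendronate,outcome,DE,2.05
alendronate,outcome,DS,19.44
alendronate,outcome,HO,26.49
alendronate,outcome,LT,0.57
alendronate,outcome,OT,51.45
denosumab,sex,F,57.07
denosumab,sex,M,28.98
denosumab,sex,Unknown,13.95
denosumab,continent,Unknown,0.04
denosumab,continent,NorthAmerica,30.56
denosumab,continent,Oceania,2.98
denosumab,continent,Africa,0.03
denosumab,continent,SouthAmerica,0.85
denosumab,continent,Europe,44.4
denosumab,continent,Asia,21.13
denosumab,reporter_group,Unknown,2.66
denosumab,reporter_group,Physician,59.29
denosumab,reporter_group,OtherHealthProfessional,20.77
denosumab,reporter_group,Consumer,14.29
denosumab,reporter_group,Pharmacist,2.91
denosumab,reporter_group,Lawyer,0.08
denosumab,indication_group,CancerRelated,62.87
denosumab,indication_group,OsteoporosisRelated,37.13
denosumab,outcome,DE,2.54
denosumab,outcome,DS,4.24
denosumab,outcome,HO,11.8
denosumab,outcome,LT,0.41
denosumab,outcome,OT,81.01
risedronate,sex,F,86.3
risedronate,sex,M,8.68
risedronate,sex,Unknown,5.02
risedronate,continent,Unknown,17.14
risedronate,continent,NorthAmerica,17.55
risedronate,continent,Oceania,0.82
risedronate,continent,Africa,0.41
risedronate,continent,SouthAmerica,35.1
risedronate,continent,Europe,26.12
risedronate,continent,Asia,2.86
risedronate,reporter_group,Unknown,27.12
risedronate,reporter_group,Physician,7.2
risedronate,reporter_group,OtherHealthProfessional,38.14
risedronate,reporter_group,Consumer,12.71
risedronate,reporter_group,Pharmacist,11.02
risedronate,reporter_group,Lawyer,3.81
risedronate,indication_group,CancerRelated,4.64
risedronate,indication_group,OsteoporosisRelated,95.36
risedronate,outcome,DE,1.69
risedronate,outcome,DS,6.76
risedronate,outcome,HO,28.38
risedronate,outcome,LT,3.04
risedronate,outcome,OT,60.14
ibandronate,sex,F,87.32
ibandronate,sex,M,6.24
ibandronate,sex,Unknown,6.44
ibandronate,continent,Unknown,33.89
ibandronate,continent,NorthAmerica,0
ibandronate,continent,Oceania,0.83
ibandronate,continent,Africa,51.98
ibandronate,continent,SouthAmerica,12.89
ibandronate,continent,Europe,0.42
ibandronate,continent,Asia,0
ibandronate,reporter_group,Unknown,14.97
ibandronate,reporter_group,Physician,39.71
ibandronate,reporter_group,OtherHealthProfessional,19.75
ibandronate,reporter_group,Consumer,10.81
ibandronate,reporter_group,Pharmacist,2.08
ibandronate,reporter_group,Lawyer,12.68
ibandronate,indication_group,CancerRelated,25.48
ibandronate,indication_group,OsteoporosisRelated,74.52
ibandronate,outcome,DE,1.48
ibandronate,outcome,DS,7.38
ibandronate,outcome,HO,20.3
ibandronate,outcome,LT,1.29
ibandronate,outcome,OT,69.56
pamidronate,sex,F,65.98
pamidronate,sex,M,25.32
pamidronate,sex,Unknown,8.7
pamidronate,continent,Unknown,61.64
pamidronate,continent,NorthAmerica,3.58
pamidronate,continent,Oceania,2.05
pamidronate,continent,Africa,25.58
pamidronate,continent,SouthAmerica,6.65
pamidronate,continent,Europe,0.51
pamidronate,continent,Asia,0
pamidronate,reporter_group,Unknown,3.58
pamidronate,reporter_group,Physician,8.95
pamidronate,reporter_group,OtherHealthProfessional,34.53
pamidronate,reporter_group,Consumer,0
pamidronate,reporter_group,Pharmacist,1.02
pamidronate,reporter_group,Lawyer,51.92
pamidronate,indication_group,CancerRelated,88.24
pamidronate,indication_group,OsteoporosisRelated,11.76
pamidronate,outcome,DE,2.3
pamidronate,outcome,DS,33.61
pamidronate,outcome,HO,4.26
pamidronate,outcome,LT,0.33
pamidronate,outcome,OT,59.51
romosozumab,sex,F,88.89
romosozumab,sex,M,5.56
romosozumab,sex,Unknown,5.56
romosozumab,continent,Unknown,27.78
romosozumab,continent,NorthAmerica,0
romosozumab,continent,Oceania,0
romosozumab,continent,Africa,5.56
romosozumab,continent,SouthAmerica,66.67
romosozumab,continent,Europe,0
romosozumab,continent,Asia,0
romosozumab,reporter_group,Unknown,11.11
romosozumab,reporter_group,Physician,83.33
romosozumab,reporter_group,OtherHealthProfessional,0
romosozumab,reporter_group,Consumer,5.56
romosozumab,reporter_group,Pharmacist,0
romosozumab,reporter_group,Lawyer,0
romosozumab,indication_group,CancerRelated,0
romosozumab,indication_group,OsteoporosisRelated,100
romosozumab,outcome,DE,0
romosozumab,outcome,DS,4.55
romosozumab,outcome,HO,18.18
romosozumab,outcome,LT,0
romosozumab,outcome,OT,77.27
etidronate,sex,F,66.67
etidronate,sex,M,33.33
etidronate,continent,Unknown,66.67
etidronate,continent,NorthAmerica,0
etidronate,continent,Oceania,0
etidronate,continent,SouthAmerica,33.33
etidronate,continent,Europe,0
etidronate,continent,Asia,0
etidronate,reporter_group,Unknown,0
etidronate,reporter_group,Physician,66.67
etidronate,reporter_group,OtherHealthProfessional,33.33
etidronate,reporter_group,Consumer,0
etidronate,reporter_group,Pharmacist,0
etidronate,reporter_group,Lawyer,0
etidronate,indication_group,CancerRelated,0
etidronate,indication_group,OsteoporosisRelated,100
etidronate,outcome,DE,0
etidronate,outcome,DS,4.55
etidronate,outcome,HO,18.18
etidronate,outcome,LT,0
etidronate,outcome,OT,77.27
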