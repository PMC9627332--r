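ingredient,variable,category,count
zoledronic acid,sex,F,4149
zoledronic acid,sex,M,2975
zoledronic acid,sex,Unknown,490
alendronate,sex,F,2025
alendronate,sex,M,249
alendronate,sex,Unknown,244
denosumab,sex,F,4095
denosumab,sex,M,2079
denosumab,sex,Unknown,1001
risedronate,sex,F,189
risedronate,sex,M,19
risedronate,sex,Unknown,11
ibandronate,sex,F,420
ibandronate,sex,M,30
ibandronate,sex,Unknown,31
pamidronate,sex,F,258
pamidronate,sex,M,99
pamidronate,sex,Unknown,34
romosozumab,sex,F,16
romosozumab,sex,M,1
romosozumab,sex,Unknown,1
etidronate,sex,F,2
etidronate,sex,M,1
zoledronic acid,continent,NorthAmerica,1468
zoledronic acid,continent,Oceania,59
zoledronic acid,continent,Africa,22
zoledronic acid,continent,SouthAmerica,178
zoledronic acid,continent,Europe,3901
zoledronic acid,continent,Asia,1764
zoledronic acid,continent,Unknown,222
alendronate,continent,NorthAmerica,1508
alendronate,continent,Oceania,3
alendronate,continent,Africa,0
alendronate,continent,SouthAmerica,6
alendronate,continent,Europe,832
alendronate,continent,Asia,158
alendronate,continent,Unknown,11
denosumab,continent,NorthAmerica,2193
denosumab,continent,Oceania,214
denosumab,continent,Africa,2
denosumab,continent,SouthAmerica,61
denosumab,continent,Europe,3186
denosumab,continent,Asia,1516
denosumab,continent,Unknown,3
risedronate,continent,NorthAmerica,43
risedronate,continent,Oceania,2
risedronate,continent,Africa,1
risedronate,continent,SouthAmerica,86
risedronate,continent,Europe,64
risedronate,continent,Asia,7
risedronate,continent,Unknown,42
ibandronate,continent,NorthAmerica,0
ibandronate,continent,Oceania,4
ibandronate,continent,Africa,250
ibandronate,continent,SouthAmerica,62
ibandronate,continent,Europe,2
ibandronate,continent,Asia,0
ibandronate,continent,Unknown,163
pamidronate,continent,NorthAmerica,14
pamidronate,continent,Oceania,8
pamidronate,continent,Africa,100
pamidronate,continent,SouthAmerica,26
pamidronate,continent,Europe,2
pamidronate,continent,Asia,0
pamidronate,continent,Unknown,241
romosozumab,continent,NorthAmerica,0
romosozumab,continent,Oceania,0
romosozumab,continent,Africa,1
romosozumab,continent,SouthAmerica,12
romosozumab,continent,Europe,0
romosozumab,continent,Asia,0
romosozumab,continent,Unknown,5
etidronate,continent,NorthAmerica,0
etidronate,continent,Oceania,0
etidronate,continent,SouthAmerica,1
etidronate,continent,Europe,0
etidronate,continent,Asia,0
etidronate,continent,Unknown,2
zoledronic acid,reporter_group,Physician,1477
zoledronic acid,reporter_group,OtherHealthProfessional,4473
zoledronic acid,reporter_group,Consumer,939
zoledronic acid,reporter_group,Pharmacist,134
zoledronic acid,reporter_group,Lawyer,63
zoledronic acid,reporter_group,Unknown,528
alendronate,reporter_group,Physician,814
alendronate,reporter_group,OtherHealthProfessional,954
alendronate,reporter_group,Consumer,422
alendronate,reporter_group,Pharmacist,36
alendronate,reporter_group,Lawyer,108
alendronate,reporter_group,Unknown,184
denosumab,reporter_group,Physician,4254
denosumab,reporter_group,OtherHealthProfessional,1490
denosumab,reporter_group,Consumer,1025
denosumab,reporter_group,Pharmacist,209
denosumab,reporter_group,Lawyer,6
denosumab,reporter_group,Unknown,191
risedronate,reporter_group,Physician,17
risedronate,reporter_group,OtherHealthProfessional,90
risedronate,reporter_group,Consumer,30
risedronate,reporter_group,Pharmacist,26
risedronate,reporter_group,Lawyer,9
risedronate,reporter_group,Unknown,64
ibandronate,reporter_group,Physician,191
ibandronate,reporter_group,OtherHealthProfessional,95
ibandronate,reporter_group,Consumer,52
ibandronate,reporter_group,Pharmacist,10
ibandronate,reporter_group,Lawyer,61
ibandronate,reporter_group,Unknown,72
pamidronate,reporter_group,Physician,35
pamidronate,reporter_group,OtherHealthProfessional,135
pamidronate,reporter_group,Consumer,0
pamidronate,reporter_group,Pharmacist,4
pamidronate,reporter_group,Lawyer,203
pamidronate,reporter_group,Unknown,14
romosozumab,reporter_group,Physician,15
romosozumab,reporter_group,OtherHealthProfessional,0
romosozumab,reporter_group,Consumer,1
romosozumab,reporter_group,Pharmacist,0
romosozumab,reporter_group,Lawyer,0
romosozumab,reporter_group,Unknown,2
etidronate,reporter_group,Physician,2
etidronate,reporter_group,OtherHealthProfessional,1
etidronate,reporter_group,Consumer,0
etidronate,reporter_group,Pharmacist,0
etidronate,reporter_group,Lawyer,0
etidronate,reporter_group,Unknown,0
zoledronic acid,indication_group,CancerRelated,4963
zoledronic acid,indication_group,OsteoporosisRelated,550
alendronate,indication_group,CancerRelated,35
alendronate,indication_group,OsteoporosisRelated,1877
denosumab,indication_group,CancerRelated,2877
denosumab,indication_group,OsteoporosisRelated,1699
risedronate,indication_group,CancerRelated,7
risedronate,indication_group,OsteoporosisRelated,144
ibandronate,indication_group,CancerRelated,92
ibandronate,indication_group,OsteoporosisRelated,269
pamidronate,indication_group,CancerRelated,105
pamidronate,indication_group,OsteoporosisRelated,14
romosozumab,indication_group,CancerRelated,0
romosozumab,indication_group,OsteoporosisRelated,16
etidronate,indication_group,CancerRelated,0
etidronate,indication_group,OsteoporosisRelated,1
zoledronic acid,outcome,DE,604
zoledronic acid,outcome,DS,665
zoledronic acid,outcome,HO,1581
zoledronic acid,outcome,LT,53
zoledronic acid,outcome,OT,6272
alendronate,outcome,DE,87
alendronate,outcome,DS,824
alendronate,outcome,HO,1123
alendronate,outcome,LT,24
alendronate,outcome,OT,2181
denosumab,outcome,DE,213
denosumab,outcome,DS,355
denosumab,outcome,HO,989
denosumab,outcome,LT,34
denosumab,outcome,OT,6789
risedronate,outcome,DE,5
risedronate,outcome,DS,20
risedronate,outcome,HO,84
risedronate,outcome,LT,9
risedronate,outcome,OT,178
ibandronate,outcome,DE,8
ibandronate,outcome,DS,40
ibandronate,outcome,HO,110
ibandronate,outcome,LT,7
ibandronate,outcome,OT,377
pamidronate,outcome,DE,14
pamidronate,outcome,DS,205
pamidronate,outcome,HO,26
pamidronate,outcome,LT,2
pamidronate,outcome,OT,363
romosozumab,outcome,DE,0
romosozumab,outcome,DS,1
romosozumab,outcome,HO,4
romosozumab,outcome,LT,0
romosozumab,outcome,OT,17
etidronate,outcome,DE,0
etidronate,outcome,DS,1
etidronate,outcome,HO,4
etidronate,outcome,LT,0
etidronate,outcome,OT,17
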