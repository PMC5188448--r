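"subject_id","age","sex","center","arm","bmi","t2d_prevalent","followup_years","t2d_incident","energy","meddiet","alcohol","smoking","physact","dyslipidemia","hypertension","snp:rs7903146","snp:rs12899811","snp:rs11634397","snp:rs11257655","snp:rs163184","snp:rs6798189","snp:rs4402960","snp:rs3802177","snp:rs10842994","snp:rs2261181","obesity"
"S00001",63.9,"male","C2","control",23.9,TRUE,,FALSE,2694,9,1.2,FALSE,344.8,TRUE,TRUE,"CT","AG","AG","CT","TG","AA","GG","AA","CC","CC",FALSE
"S00002",65.3,"male","C5","MedDiet+EVOO",25.6,TRUE,,FALSE,2069,9,0.1,TRUE,3.3,TRUE,TRUE,"CT","GG","AA","CC","TG","GG","GT","AG","TC","CC",FALSE
"S00003",71.6,"male","C2","MedDiet+EVOO",28.6,FALSE,4.06,FALSE,1776,8,6,TRUE,679.1,FALSE,TRUE,"CC","AA","GG","CC","TG","AA","TT","AA","TC","CC",FALSE
"S00004",71.1,"female","C5","MedDiet+nuts",21.9,TRUE,,FALSE,3116,6,0,FALSE,20.1,TRUE,TRUE,"CT","GG","AA","CC","TT","AA","GT","AA","TC","CC",FALSE
"S00005",64.2,"male","C5","control",31.2,FALSE,8.13,FALSE,2068,6,1.3,FALSE,505.2,TRUE,TRUE,"CC","AG","AG","CT","TG","AG","GG","AA","CC","CC",TRUE
"S00006",55,"female","C6","MedDiet+EVOO",28.4,FALSE,5.62,FALSE,2139,13,0,FALSE,374,TRUE,TRUE,"CC","AG","AG","CC","TG","AG","GG","AG","TC","CC",FALSE
"S00007",78.7,"male","C2","MedDiet+EVOO",33.1,TRUE,,FALSE,3090,10,15.4,FALSE,79.5,FALSE,TRUE,"CC","AA","AG","CC","GG","AG","GG","AG","TC","CC",TRUE
"S00008",59.3,"male","C2","MedDiet+EVOO",26.7,TRUE,,FALSE,1655,8,0.5,FALSE,370.3,TRUE,FALSE,"CT","AG","AG","CC","GG","AG","GG","AG","CC","CC",FALSE
"S00009",64,"female","C2","MedDiet+EVOO",28.7,FALSE,8.47,FALSE,2224,10,0,FALSE,414,TRUE,TRUE,"CC","GG","AG","CC","TT","AA","GG","AA","CC","CC",FALSE
"S00010",68.3,"female","C2","MedDiet+EVOO",29.8,TRUE,,FALSE,1557,9,21.2,FALSE,462.4,TRUE,TRUE,"CT","AA","AA","CT","TG","AG","GT","AA","CC","CC",FALSE
"S00011",69.6,"male","C2","control",34.2,TRUE,,FALSE,2511,11,120.4,FALSE,462.5,FALSE,TRUE,"CC","AA","AG","CC","TG","AG","TT","AG","CC","CC",TRUE
"S00012",59.4,"female","C3","control",27.9,TRUE,,FALSE,1593,13,0,FALSE,384.5,TRUE,TRUE,"TT","AG","AG","CC","GG","AG","GG","AA","TC","CC",FALSE
"S00013",68.9,"female","C1","MedDiet+nuts",33.1,TRUE,,FALSE,1885,12,1.6,FALSE,272.2,TRUE,TRUE,"CT","AG","AA","CC","TT","AA","GG","AG","CC","CC",TRUE
"S00014",72.5,"female","C7","MedDiet+EVOO",31.2,TRUE,,FALSE,3764,10,1.6,TRUE,331.1,TRUE,FALSE,"CT","AG","GG","CC","TG","AA","TT","GG","CC","CC",TRUE
"S00015",69.9,"male","C7","control",32.4,FALSE,7.67,FALSE,2638,9,27.5,FALSE,5.7,TRUE,TRUE,"CC","AG","AA","CC","TT","AA","GT","AA","TC","CC",TRUE
"S00016",72.4,"female","C2","control",25.2,FALSE,2.67,FALSE,2843,6,1.7,FALSE,115.9,TRUE,FALSE,"CC","AG","AA","CT","TG","AA","GG","AG","TC","CC",FALSE
"S00017",61.5,"male","C5","MedDiet+EVOO",24.4,FALSE,3.68,FALSE,2551,10,12.9,TRUE,7,TRUE,FALSE,"CT","AG","GG","TT","TG","AA","GG","AA","CC","CC",FALSE
"S00018",66.2,"female","C4","MedDiet+nuts",26.7,FALSE,2.79,FALSE,3755,9,4.6,FALSE,87.7,FALSE,FALSE,"CT","AG","AA","CT","TG","AG","GT","AA","CC","CT",FALSE
"S00019",73.8,"male","C2","MedDiet+EVOO",25.8,FALSE,6.22,FALSE,1635,8,9.4,TRUE,222.3,TRUE,FALSE,"CT","AA","AA","CC","TG","AG","GG","AA","CC","CC",FALSE
"S00020",70.2,"male","C6","MedDiet+nuts",28.6,FALSE,3.42,FALSE,2860,4,1.6,FALSE,995.9,TRUE,TRUE,"CC","AA","AG","CC","TT","AG","GT","AA","TC","CC",FALSE
"S00021",69.5,"female","C1","control",30.1,TRUE,,FALSE,2039,8,2.7,FALSE,86.6,TRUE,FALSE,"CC","AA","AG","CT","TT","AA","GG","AG","CC","CC",TRUE
"S00022",73.6,"male","C6","MedDiet+nuts",25.8,FALSE,6.82,FALSE,2877,10,0.1,FALSE,478.8,FALSE,TRUE,"CC","AA","AA","CT","TG","AA","TT","AA","TC","CC",FALSE
"S00023",64.2,"female","C4","MedDiet+EVOO",26.8,TRUE,,FALSE,2585,11,3.8,FALSE,283,FALSE,TRUE,"CC","AA","GG","CC","TG","AG","TT","AG","CC","CC",FALSE
"S00024",70.9,"male","C4","control",25.1,FALSE,4.69,FALSE,1130,8,0,FALSE,290.2,TRUE,TRUE,"CC","AA","GG","CC","GG","AG","GT","AG","TC","CC",FALSE
"S00025",61.9,"male","C1","MedDiet+nuts",31.7,TRUE,,FALSE,2136,9,0.8,FALSE,50.7,TRUE,TRUE,"CT","AG","AG","TT","TG","AG","GG","AA","TC","CC",TRUE
"S00026",65.4,"male","C5","control",27.6,FALSE,3.76,FALSE,2532,10,0.7,FALSE,44.8,FALSE,TRUE,"CT","AA","AA","CC","TT","AA","GT","AA","TC","CC",FALSE
"S00027",68,"female","C5","control",26.8,TRUE,,FALSE,1450,9,0.7,FALSE,63.9,FALSE,TRUE,"CC","AA","AA","CT","GG","GG","GT","AA","CC","CC",FALSE
"S00028",70.5,"male","C6","control",27.9,FALSE,6.51,FALSE,3189,8,22.4,FALSE,278.2,TRUE,TRUE,"TT","AA","AG","CT","TG","AG","GT","AG","CC","CC",FALSE
"S00029",55,"female","C7","MedDiet+nuts",39.2,FALSE,4.61,FALSE,2571,10,0,FALSE,41.3,TRUE,TRUE,"CC","AG","AG","CC","TG","AA","GG","GG","TC","CC",TRUE
"S00030",74,"female","C6","control",28.3,FALSE,7.22,FALSE,840,11,5,FALSE,576.8,FALSE,FALSE,"CT","AA","AA","CT","TG","AG","GG","AG","TC","CC",FALSE
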