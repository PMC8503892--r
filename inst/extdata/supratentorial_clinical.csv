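id,age_years,sex,nanostring_diagnosis,ngs_fusion,original_diagnosis,relapse_months,dod_months,adf_months,rt,chemotherapy
1,12,M,RELA+,ZFTA-RELA,EPN III,No,No,168,Local,EPN
2,12,F,RELA+,ZFTA-RELA,EPN III,No,No,168,Local,EPN
3,5,M,RELA+,ZFTA-RELA,EPN III,No,No,120,Local,EPN
4,3,M,RELA+,ZFTA-RELA,EPN III,No,No,60,Local,EPN
5,6,M,RELA+,ZFTA-RELA,EPN III,No,No,77,Local,EPN
6,2,F,RELA+,ZFTA-RELA,EPN III,134/distant,No,168,No,For children <3 years old
7,11,F,RELA+,Not detected,EPN III,No,No,72,Local,EPN
8,12,M,RELA+,ZFTA-RELA,EPN III,46/local,No,288,Local,No but EPN on relapse
9,14,M,RELA+,ZFTA-RELA,EPN III,No,No,24,Local,EPN
10,1,M,RELA+,ZFTA-RELA,PNET,22,42,-,No,MB/PNET
11,7,F,YAP1+,YAP1-MAMLD1,EPN II,No,Yes,-,CSI,EPN
12,1,M,NC,ZFTA-MAML2,EPN II,No,No,156,No,For children <3 years old
13,17,F,NC,Not detected,EPN III,No,No,168,Local,EPN
14,16,F,NC,Not detected,EPN II,No,No,216,Local,EPN
15,2,M,NC,Not detected,EPN III,No,No,96,No,For children <3 years old
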