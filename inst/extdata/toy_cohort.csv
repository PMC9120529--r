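SUBJECT_ID,VENTRICLES,HIPPOCAMPUS,WHOLEBRAIN,ENTORHINAL,FUSIFORM,MIDTEMP,ICV,FDG,PIB,AV45,RAVLT_IMMEDIATE,RAVLT_LEARNING,RAVLT_FORGETTING,RAVLT_PERC_FORGETTING,FAQ,ECOG_PT_MEM,ECOG_PT_LANG,ECOG_PT_VISSPAT,ECOG_PT_PLAN,ECOG_PT_ORGAN,ECOG_PT_DIVATT,ECOG_PT_TOTAL,ECOG_SP_MEM,ECOG_SP_LANG,ECOG_SP_VISSPAT,ECOG_SP_PLAN,ECOG_SP_ORGAN,ECOG_SP_DIVATT,ECOG_SP_TOTAL,ABETA,PTAU,TAU,AGE,GENDER,EDUCATION,APOE4,ADAS11,ADAS13,MoCA,CDR,CDRSB,MMSE_M0,MMSE_M6,MMSE_M12,MMSE_M24,LABEL_24M
TOY001,7.74,2.22,8.79,3.43,4.14,4.27,6.25,2.61,2.74,5.38,2.01,5,4.17,4.98,5.17,5.3,5.51,2.25,4.74,3.68,3.54,2.6,4.89,5.94,0.77,4.99,2.93,8.62,2.23,5.17,3.3,368.7,64.7,0,12,2,8.9,23.9,18,1,3,21,20,27,28,AD
TOY002,3.87,4.44,4.14,3.3,6.31,5.37,3.09,6.22,2.08,5.24,2.06,7.25,7.23,3.4,6.79,3.83,2.41,2.7,7.95,7.5,7,5.38,7.13,2.51,5.55,6.52,3.74,3.35,2.39,7.71,2.82,786.4,73,1,15,0,16.2,24.4,27,0.5,3.8,28,29,21,25,MCI-C
TOY003,5.73,4.73,4.49,0.17,5.64,6.16,3.91,4.57,5.16,4.95,5.25,7.88,4.04,3.93,4.54,5.74,3.08,3.59,4.57,4.46,7.52,7.6,6.63,7.76,3.62,5.08,6.17,7.29,3.46,6.45,4.03,167.6,83.3,0,16,1,17.1,10.3,20,0.5,7.1,22,27,23,22,MCI-NC
TOY004,6.27,6.27,1.47,5.07,3.43,7.8,6.16,4.63,6.31,5.22,3.01,2.81,4.13,7.58,6.67,5.59,7.17,2.89,2.43,6.9,7.5,2.93,4.62,7.41,5.89,6.47,4.17,5.06,3.95,3.33,4.33,262,75.2,1,20,1,28.8,19,28,0.5,1.3,22,27,23,28,CN
TOY005,5.81,4.43,5.92,5.41,8.15,3.55,6.54,6.87,7.4,4.03,5,4.77,6.39,4.65,1.51,4.44,5.81,3.71,5.77,2.6,2.24,3.52,-0.4,6.65,3.38,4.71,3.43,3.33,4.96,6.47,4.69,497.4,83,0,14,1,27.6,32.2,10,0,4.3,28,25,27,27,AD
TOY006,4.79,-0.31,3.72,4.28,6.29,7.61,5.93,6.64,7.09,3.99,4.14,7.4,2.89,2.86,8.38,2.33,6.17,4.63,4.3,4.07,9.1,5.09,5.12,1.67,9.42,4.88,5.33,4.86,6.34,3.26,4.51,383.9,79.4,1,16,1,28.5,20.3,20,0,0.3,30,25,20,26,MCI-C
TOY007,8.02,0.12,5.91,6.52,5.18,5.67,3.23,7.78,2.99,1.68,3.77,4.06,4.92,5.33,6.73,6.4,8.63,2.6,3.96,4.46,7.03,2.96,6.15,3.86,4.75,5.96,2.53,6.49,4.13,4.09,8.78,754.4,76.5,0,16,0,24.3,8.2,26,0.5,4.5,30,22,29,28,MCI-NC
TOY008,4.81,7.64,6.41,3.55,5.55,7.08,2.8,4.05,8.7,4.24,0.95,4.9,1.9,4.27,4.7,6.11,5.26,9.07,2.86,4.22,4.95,4.23,5.09,6.27,4.05,6.99,7.09,4.15,2.77,7.38,2.23,798.9,80.3,1,13,2,7.3,31,26,0,7.9,26,29,24,27,CN
TOY009,9.04,4.39,7.07,2.26,6.36,6.84,8.03,6.3,3.67,3.97,2.55,4.83,7.33,6.18,2.1,3.33,1,5.22,5.86,7.7,6.41,6.75,5.31,5.09,4.67,2.51,4.03,3.46,6.21,4.42,4.17,134.9,83.2,0,20,1,5.4,25.8,17,1,4.7,29,20,20,22,
TOY010,4.87,1.44,3.78,5.87,5.18,6.44,5.52,7.78,5.21,10.4,5.36,3.22,4.45,7.86,6.29,1.81,5.67,4.83,4.65,4.95,3.06,6.94,5.86,5.7,6.73,4.93,5.38,5.31,5.55,6.66,5.7,75,65.8,1,14,2,13.3,10.2,20,0.5,2.4,20,29,20,23,MCI-C
TOY011,7.61,4.66,6.01,3.38,-0.99,2.91,5.18,2.78,4.16,2.28,6.14,4.11,4.06,3.01,5.97,5.41,7.34,5.99,6.03,5.49,2.81,5.77,4.21,9.92,5.19,4.86,5.1,6.98,7.31,4.42,8.26,1500,66.4,0,19,2,11,19.1,27,2,8.9,21,26,29,22,MCI-NC
TOY012,9.57,7.43,1.57,7.89,5.57,4.82,4.76,3.28,4.76,5.27,4.01,4.94,2.52,5.91,4.99,4.31,9.12,5.07,4.53,3.12,5.1,1.3,7.62,3.36,1.75,3.48,5,4.85,1.64,1.85,5.18,644.2,64.2,1,13,0,24.8,21.2,10,2,1.3,23,28,NA,26,CN
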