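experiment,classifier,sensitivity,precision,f1,auc,accuracy,fnr
cbis_original,ESKNN,92.05,92.05,92.05,0.96,92,7.95
cbis_original,F-KNN,91.9,91.85,91.87,0.92,91.8,8.1
cbis_original,C-SVM,90.35,90.35,90.35,0.96,90.4,9.65
cbis_original,MGSVM,88.7,88.7,88.7,0.95,88.7,11.3
cbis_original,MNN,88.7,88.65,88.67,0.93,88.7,11.3
cbis_original,Wide NN,88.4,88.45,88.42,0.94,88.4,11.6
cbis_original,WKNN,88.1,88.1,88.1,0.95,88.1,11.9
cbis_original,QSVM,87.6,87.6,87.6,0.95,87.6,12.4
cbis_original,N3,87.55,87.55,87.55,0.92,87.5,12.45
cbis_original,BN2,87.25,87.25,87.25,0.92,87.2,12.75
cbis_enhanced,ESKNN,95.05,95,95.02,0.97,95,4.95
cbis_enhanced,F-KNN,94.7,94.7,94.7,0.95,94.7,5.3
cbis_enhanced,C-SVM,92.15,92.15,92.15,0.97,92.1,7.85
cbis_enhanced,MGSVM,91.5,91.5,91.5,0.97,91.5,8.5
cbis_enhanced,MNN,90.55,90.55,90.55,0.94,90.6,9.45
cbis_enhanced,Wide NN,90.5,90.5,90.5,0.96,90.5,9.5
cbis_enhanced,WKNN,90,90,90,0.96,89.9,10
cbis_enhanced,QSVM,90.4,90.45,90.42,0.96,90.4,9.6
cbis_enhanced,N3,90.1,90.15,90.12,0.94,90.1,9.9
cbis_enhanced,BN2,89.85,89.85,89.85,0.94,89.9,10.15
cbis_fused,ESKNN,94.15,94.15,94.15,0.97,94.1,5.85
cbis_fused,F-KNN,93.75,93.75,93.75,0.94,93.8,6.25
cbis_fused,C-SVM,93.6,93.6,93.6,0.99,93.6,6.4
cbis_fused,MGSVM,93.1,93.1,93.1,0.98,93.1,6.9
cbis_fused,MNN,92.2,92.25,92.22,0.98,92.2,7.8
cbis_fused,Wide NN,92.1,92.1,92.1,0.98,92.1,7.9
cbis_fused,WKNN,91.75,91.75,91.75,0.97,91.7,8.25
cbis_fused,QSVM,93.15,93.2,93.17,0.98,93.2,6.85
cbis_fused,N3,90.35,90.3,90.32,0.94,90.3,9.65
cbis_fused,BN2,90.55,90.5,90.52,0.94,90.5,9.45
cbis_selected,ESKNN,95.4,95.35,95.37,0.98,95.4,4.6
cbis_selected,F-KNN,95.25,95.25,95.25,0.95,95.3,4.75
cbis_selected,C-SVM,91.75,91.75,91.75,0.97,91.8,8.25
cbis_selected,MGSVM,90.75,90.75,90.75,0.96,90.7,9.25
cbis_selected,MNN,92.05,92.05,92.05,0.97,92,7.95
cbis_selected,Wide NN,94.7,94.7,94.7,0.95,94.7,5.3
cbis_selected,WKNN,90.7,90.65,90.67,0.96,90.7,9.3
cbis_selected,QSVM,89.75,89.75,89.75,0.95,89.1,10.25
cbis_selected,N3,91.5,91.5,91.5,0.97,91.5,8.5
cbis_selected,BN2,94.9,94.85,94.87,0.98,94.9,5.1
inbreast_original,MGSVM,98.25,98.25,98.25,0.99,98.3,1.75
inbreast_original,ESKNN,98.15,98.15,98.15,0.98,98.2,1.85
inbreast_original,QSVM,98.08,98.05,98.06,1,98.1,1.95
inbreast_original,F-KNN,98.05,98.05,98.05,0.98,98.1,1.95
inbreast_original,LSVM,97.95,97.95,97.95,1,98,2.05
inbreast_original,Bi-NN,98,98,98,1,98,2
inbreast_original,EBT,97.85,97.85,97.85,0.99,97.9,2.15
inbreast_original,Tri-NN,97.9,97.9,97.9,1,97.9,2.1
inbreast_original,C-SVM,97.7,97.7,97.7,0.99,97.7,2.3
inbreast_original,N3,97.7,97.7,97.7,0.99,97.7,2.3
inbreast_enhanced,MGSVM,98.05,98.15,98.09,0.99,98.1,1.95
inbreast_enhanced,ESKNN,98,98.1,98.04,0.98,98,2
inbreast_enhanced,QSVM,97.9,98,97.94,0.99,97.9,2.1
inbreast_enhanced,F-KNN,97.9,98,97.94,0.98,97.9,2.1
inbreast_enhanced,LSVM,97.25,95.5,96.36,1,97.3,2.75
inbreast_enhanced,Bi-NN,97.35,97.3,97.32,1,97.3,2.65
inbreast_enhanced,EBT,96.45,96.5,96.47,0.99,96.5,3.55
inbreast_enhanced,Tri-NN,97.35,97.35,97.35,0.99,97.3,2.65
inbreast_enhanced,C-SVM,97.85,97.85,97.85,0.99,97.7,2.15
inbreast_enhanced,N3,97.7,97.7,97.7,0.99,97.7,2.3
inbreast_fused,MGSVM,99.55,99.6,99.57,1,99.6,0.45
inbreast_fused,ESKNN,97.9,98,97.94,0.99,97.9,2.1
inbreast_fused,QSVM,99.45,99.5,99.47,1,99.5,0.55
inbreast_fused,F-KNN,97.8,97.9,97.84,0.98,97.9,2.2
inbreast_fused,LSVM,99.45,99.5,99.47,1,99.5,0.55
inbreast_fused,Bi-NN,99.15,99.2,99.17,1,99.1,0.85
inbreast_fused,EBT,98.85,98.9,98.87,1,98.9,1.15
inbreast_fused,Tri-NN,99.15,99.2,99.17,1,99.1,0.85
inbreast_fused,CSVM,99.45,99.5,99.47,1,99.5,0.55
inbreast_fused,N3,99.3,99.35,99.32,1,99.3,0.7
inbreast_selected,MGSVM,99.05,99.1,99.07,1,99.1,0.95
inbreast_selected,ESKNN,98,98.1,98.04,1,98,2
inbreast_selected,QSVM,99.2,99.25,99.22,1,99.2,0.8
inbreast_selected,F-KNN,97.55,97.55,97.55,0.98,97.6,2.45
inbreast_selected,LSVM,99.2,99.2,99.2,1,99.2,0.8
inbreast_selected,Bi-NN,98.2,98.2,98.2,1,98.2,1.8
inbreast_selected,EBT,98.2,98.2,98.2,1,98.3,1.8
inbreast_selected,Tri-NN,98.6,98.6,98.6,0.99,98.5,1.4
inbreast_selected,CSVM,99.4,99.4,99.4,1,99.4,0.6
inbreast_selected,N3,99.05,99.05,99.05,1,99.1,0.95
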