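table,model,precision,recall,f_reported
overall,textconvonet,90.28,90.30,90.29
overall,decision_tree,72.94,74.33,73.62
overall,random_forest,81.90,74.73,78.15
overall,svm,67.53,67.47,67.50
overall,stacking,80.70,77.23,78.93
cv5,textconvonet,89.06,88.94,89.0
per_class_misinformation,textconvonet,0.88,0.94,0.91
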