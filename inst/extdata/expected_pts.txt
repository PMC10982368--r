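Cystitis
Pyelonephritis acute
Rhinitis
Blood pressure increased
Head discomfort
Dry throat
Dry mouth
Bowel movement irregularity
Blood pressure systolic increased
Urinary retention
Dysuria
Cystitis interstitial
Blood pressure abnormal
Cystitis haemorrhagic
Atrial fibrillation
Tachycardia
Atrial tachycardia
Hypertension
Hypertensive crisis
Accelerated hypertension
Malignant hypertension
Essential hypertension
Dry eye
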