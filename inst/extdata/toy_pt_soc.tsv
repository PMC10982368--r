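pt	soc
Cystitis	Infections and infestations
Pyelonephritis acute	Infections and infestations
Rhinitis	Infections and infestations
Kidney infection	Infections and infestations
Nasopharyngitis	Infections and infestations
Blood pressure increased	Investigations
Electrocardiogram QT prolonged	Investigations
Heart rate irregular	Investigations
Blood pressure systolic increased	Investigations
Intraocular pressure increased	Investigations
Blood urine present	Investigations
Antineutrophil cytoplasmic antibody increased	Investigations
Blood pressure abnormal	Investigations
Dementia	Nervous system disorders
Transient ischaemic attack	Nervous system disorders
Parkinson's disease	Nervous system disorders
Head discomfort	Nervous system disorders
Myasthenia gravis	Nervous system disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Muscle tightness	Musculoskeletal and connective tissue disorders
Muscle atrophy	Musculoskeletal and connective tissue disorders
Back pain	Musculoskeletal and connective tissue disorders
Dry throat	Respiratory, thoracic and mediastinal disorders
Hyperventilation	Respiratory, thoracic and mediastinal disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Hallucination, visual	Psychiatric disorders
Abnormal dreams	Psychiatric disorders
Apathy	Psychiatric disorders
Eating disorder	Psychiatric disorders
Delirium	Psychiatric disorders
Insomnia	Psychiatric disorders
Anti-neutrophil cytoplasmic antibody positive vasculitis	Immune system disorders
Angioedema	Immune system disorders
Hypersensitivity	Immune system disorders
Petechiae	Skin and subcutaneous tissue disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Generalised oedema	General disorders and administration site conditions
Thirst	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Urinary retention	Renal and urinary disorders
Dysuria	Renal and urinary disorders
Nocturia	Renal and urinary disorders
Urinary incontinence	Renal and urinary disorders
Pollakiuria	Renal and urinary disorders
Haematuria	Renal and urinary disorders
Micturition urgency	Renal and urinary disorders
Bladder pain	Renal and urinary disorders
Hypertonic bladder	Renal and urinary disorders
Urine flow decreased	Renal and urinary disorders
Postrenal failure	Renal and urinary disorders
Cystitis interstitial	Renal and urinary disorders
Cystitis haemorrhagic	Renal and urinary disorders
Hydronephrosis	Renal and urinary disorders
Bladder spasm	Renal and urinary disorders
Neurogenic bladder	Renal and urinary disorders
Urge incontinence	Renal and urinary disorders
Erectile dysfunction	Reproductive system and breast disorders
Benign prostatic hyperplasia	Reproductive system and breast disorders
Vulvovaginal discomfort	Reproductive system and breast disorders
Dry mouth	Gastrointestinal disorders
Lip swelling	Gastrointestinal disorders
Swollen tongue	Gastrointestinal disorders
Mouth swelling	Gastrointestinal disorders
Peptic ulcer	Gastrointestinal disorders
Bowel movement irregularity	Gastrointestinal disorders
Colitis ischaemic	Gastrointestinal disorders
Cheilitis	Gastrointestinal disorders
Lip disorder	Gastrointestinal disorders
Lip oedema	Gastrointestinal disorders
Nausea	Gastrointestinal disorders
Constipation	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Atrial fibrillation	Cardiac disorders
Arrhythmia	Cardiac disorders
Palpitations	Cardiac disorders
Tachycardia	Cardiac disorders
Angina pectoris	Cardiac disorders
Extrasystoles	Cardiac disorders
Atrial flutter	Cardiac disorders
Ventricular extrasystoles	Cardiac disorders
Sinus node dysfunction	Cardiac disorders
Cardiac fibrillation	Cardiac disorders
Cardiac discomfort	Cardiac disorders
Atrial tachycardia	Cardiac disorders
Acute myocardial infarction	Cardiac disorders
Hypertension	Vascular disorders
Hypertensive crisis	Vascular disorders
Vasculitis	Vascular disorders
Malignant hypertension	Vascular disorders
Accelerated hypertension	Vascular disorders
Essential hypertension	Vascular disorders
Dry eye	Eye disorders
Eyelid oedema	Eye disorders
Glaucoma	Eye disorders
Retinal vein occlusion	Eye disorders
Vision blurred	Eye disorders
Visual impairment	Eye disorders
Hyperglycaemia	Metabolism and nutrition disorders
Decreased appetite	Metabolism and nutrition disorders
Fall	Injury, poisoning and procedural complications
Overdose	Injury, poisoning and procedural complications
Product quality issue	Product issues
Hip arthroplasty	Surgical and medical procedures
Homelessness	Social circumstances
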