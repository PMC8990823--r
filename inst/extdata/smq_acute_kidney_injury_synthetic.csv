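smq_name,scope,pt
Acute kidney injury,narrow,Acute kidney injury
Acute kidney injury,narrow,Anuria
Acute kidney injury,narrow,Azotaemia
Acute kidney injury,narrow,Blood creatinine abnormal
Acute kidney injury,narrow,Blood creatinine increased
Acute kidney injury,narrow,Creatinine renal clearance abnormal
Acute kidney injury,narrow,Creatinine renal clearance decreased
Acute kidney injury,narrow,Dialysis
Acute kidney injury,narrow,Glomerular filtration rate abnormal
Acute kidney injury,narrow,Glomerular filtration rate decreased
Acute kidney injury,narrow,Nephropathy toxic
Acute kidney injury,narrow,Oliguria
Acute kidney injury,narrow,Prerenal failure
Acute kidney injury,narrow,Renal failure
Acute kidney injury,narrow,Renal failure acute
Acute kidney injury,narrow,Renal impairment
Acute kidney injury,narrow,Renal tubular injury
Acute kidney injury,narrow,Renal tubular necrosis
Acute kidney injury,narrow,Subacute kidney injury
Acute kidney injury,broad,Albuminuria
Acute kidney injury,broad,Blood urea increased
Acute kidney injury,broad,Blood urea abnormal
Acute kidney injury,broad,Blood urea nitrogen/creatinine ratio increased
Acute kidney injury,broad,Crystal urine present
Acute kidney injury,broad,Glycosuria
Acute kidney injury,broad,Haematuria
Acute kidney injury,broad,Hypercreatininaemia
Acute kidney injury,broad,Myoglobin blood increased
Acute kidney injury,broad,Myoglobin urine present
Acute kidney injury,broad,Myoglobinuria
Acute kidney injury,broad,Nephritis
Acute kidney injury,broad,Nephritis interstitial
Acute kidney injury,broad,Protein urine present
Acute kidney injury,broad,Proteinuria
Acute kidney injury,broad,Renal function test abnormal
Acute kidney injury,broad,Renal tubular disorder
Acute kidney injury,broad,Rhabdomyolysis
Acute kidney injury,broad,Tubulointerstitial nephritis
Acute kidney injury,broad,Urea renal clearance decreased
Acute kidney injury,broad,Urine output decreased
Acute kidney injury,broad,Urinary casts
Acute kidney injury,broad,Hyperkalaemia
Acute kidney injury,broad,Blood potassium increased
Acute kidney injury,broad,Fluid overload
Acute kidney injury,broad,Hypervolaemia
Acute kidney injury,broad,Metabolic acidosis
Acute kidney injury,broad,Acidosis
Acute kidney injury,broad,Renal replacement therapy
Acute kidney injury,broad,Continuous haemodiafiltration
Acute kidney injury,broad,Haemodialysis
Acute kidney injury,broad,Peritoneal dialysis
Acute kidney injury,broad,Renal disorder
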