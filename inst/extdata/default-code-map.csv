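code_or_prefix,system,body_part,laterality,is_general,is_infusion_device_insertion,stem
0SRC,PCS,knee_joint,right,FALSE,FALSE,knee_joint_replacement
0SRD,PCS,knee_joint,left,FALSE,FALSE,knee_joint_replacement
0SR9,PCS,hip_joint,right,FALSE,FALSE,hip_joint_replacement
0SRB,PCS,hip_joint,left,FALSE,FALSE,hip_joint_replacement
0SP9,PCS,hip_joint,right,FALSE,FALSE,hip_joint_removal
0SPB,PCS,hip_joint,left,FALSE,FALSE,hip_joint_removal
0SPC,PCS,knee_joint,right,FALSE,FALSE,knee_joint_removal
0SPD,PCS,knee_joint,left,FALSE,FALSE,knee_joint_removal
0Y6H,PCS,lower_leg,right,FALSE,FALSE,lower_leg_detachment
0Y6J,PCS,lower_leg,left,FALSE,FALSE,lower_leg_detachment
0LS3,PCS,upper_arm_tendon,right,FALSE,FALSE,upper_arm_tendon_reposition
0LS4,PCS,upper_arm_tendon,left,FALSE,FALSE,upper_arm_tendon_reposition
0RRJ,PCS,shoulder_joint,right,FALSE,FALSE,shoulder_joint_replacement
0RRK,PCS,shoulder_joint,left,FALSE,FALSE,shoulder_joint_replacement
0QB8,PCS,femoral_shaft,right,FALSE,FALSE,femoral_shaft_excision
0QB9,PCS,femoral_shaft,left,FALSE,FALSE,femoral_shaft_excision
0QH6,PCS,upper_femur,right,FALSE,FALSE,upper_femur_fixation
0QH7,PCS,upper_femur,left,FALSE,FALSE,upper_femur_fixation
0MBL,PCS,hip_bursa,right,FALSE,FALSE,hip_bursa_excision
0MBM,PCS,hip_bursa,left,FALSE,FALSE,hip_bursa_excision
0PR7,PCS,glenoid_cavity,right,FALSE,FALSE,glenoid_replacement
0PR8,PCS,glenoid_cavity,left,FALSE,FALSE,glenoid_replacement
0JH,PCS,,none,FALSE,TRUE,infusion_device_insertion
M1710,CM,knee,unspecified,FALSE,FALSE,knee_osteoarthritis
M1711,CM,knee,right,FALSE,FALSE,knee_osteoarthritis
M1712,CM,knee,left,FALSE,FALSE,knee_osteoarthritis
M1610,CM,hip,unspecified,FALSE,FALSE,hip_osteoarthritis
M1611,CM,hip,right,FALSE,FALSE,hip_osteoarthritis
M1612,CM,hip,left,FALSE,FALSE,hip_osteoarthritis
M19021,CM,elbow,right,FALSE,FALSE,elbow_osteoarthritis
M19022,CM,elbow,left,FALSE,FALSE,elbow_osteoarthritis
M75120,CM,shoulder,unspecified,FALSE,FALSE,rotator_cuff_tear
M75121,CM,shoulder,right,FALSE,FALSE,rotator_cuff_tear
M75122,CM,shoulder,left,FALSE,FALSE,rotator_cuff_tear
S42241,CM,humerus,right,FALSE,FALSE,humerus_neck_fracture
S42242,CM,humerus,left,FALSE,FALSE,humerus_neck_fracture
Z96641,CM,hip_joint,right,FALSE,FALSE,artificial_hip_presence
Z96642,CM,hip_joint,left,FALSE,FALSE,artificial_hip_presence
Z89511,CM,lower_leg,right,FALSE,FALSE,leg_absence_below_knee
Z89512,CM,lower_leg,left,FALSE,FALSE,leg_absence_below_knee
Z4733,CM,knee_joint,none,FALSE,FALSE,knee_prosthesis_aftercare
I69354,CM,hemibody,left,FALSE,FALSE,post_stroke_hemiplegia
I69351,CM,hemibody,right,FALSE,FALSE,post_stroke_hemiplegia
C3402,CM,bronchus,left,FALSE,FALSE,bronchus_neoplasm
C3401,CM,bronchus,right,FALSE,FALSE,bronchus_neoplasm
S0501,CM,eye,right,FALSE,FALSE,eye_injury
S0502,CM,eye,left,FALSE,FALSE,eye_injury
H10501,CM,eye,right,FALSE,FALSE,blepharoconjunctivitis
H10502,CM,eye,left,FALSE,FALSE,blepharoconjunctivitis
E1152,CM,,none,TRUE,FALSE,diabetic_gangrene
I96,CM,,none,TRUE,FALSE,gangrene_nec
C7951,CM,,none,TRUE,FALSE,bone_metastasis
T84,CM,,none,TRUE,FALSE,orthopedic_device_complication
T81,CM,,none,TRUE,FALSE,procedural_complication
Y79,CM,,none,TRUE,FALSE,orthopedic_device_incident
Y83,CM,,none,TRUE,FALSE,surgical_complication
I10,CM,,none,FALSE,FALSE,hypertension
E785,CM,,none,FALSE,FALSE,hyperlipidemia
E7800,CM,,none,FALSE,FALSE,hypercholesterolemia
F17210,CM,,none,FALSE,FALSE,nicotine_dependence
F329,CM,,none,FALSE,FALSE,depression
N186,CM,,none,FALSE,FALSE,esrd
E1122,CM,,none,FALSE,FALSE,diabetic_ckd
I252,CM,,none,FALSE,FALSE,old_mi
I4510,CM,,none,FALSE,FALSE,bundle_branch_block
Z85528,CM,,none,FALSE,FALSE,neoplasm_history
G40909,CM,,none,FALSE,FALSE,epilepsy
I110,CM,,none,FALSE,FALSE,hypertensive_heart_disease
E669,CM,,none,FALSE,FALSE,obesity
G2581,CM,,none,FALSE,FALSE,restless_legs
B964,CM,,none,FALSE,FALSE,proteus_infection
I428,CM,,none,FALSE,FALSE,cardiomyopathy
G8918,CM,,none,FALSE,FALSE,postprocedural_pain
M109,CM,,none,FALSE,FALSE,gout
R200,CM,,none,FALSE,FALSE,skin_anesthesia
R591,CM,,none,FALSE,FALSE,lymphadenopathy
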