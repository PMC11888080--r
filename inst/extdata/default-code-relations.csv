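body_part_a,body_part_b,relation
knee,knee_joint,same_site
hip,hip_joint,same_site
shoulder,shoulder_joint,same_site
glenoid_cavity,shoulder,same_site
glenoid_cavity,shoulder_joint,same_site
upper_femur,femur,same_site
femoral_shaft,femur,same_site
shoulder_joint,humerus,proximity
shoulder,humerus,proximity
hip_joint,femur,proximity
hip_joint,upper_femur,proximity
knee_joint,femur,proximity
upper_leg,femur,proximity
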