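label,side,anatomical_group
HEAD_F,midline,head
HEAD_B,midline,head
C7,midline,trunk
T10,midline,trunk
R_SHO,right,upper_arm
L_SHO,left,upper_arm
R_ELB,right,upper_arm
L_ELB,left,upper_arm
R_WRI,right,forearm
L_WRI,left,forearm
SACR,midline,pelvis
R_ASIS,right,pelvis
L_ASIS,left,pelvis
R_KNE,right,leg
L_KNE,left,leg
R_ANK,right,leg
L_ANK,left,leg
R_HEE,right,foot
L_HEE,left,foot
R_TOE,right,foot
L_TOE,left,foot
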