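"name","family"
"polygon_pct_overlap","polygon"
"difference_area","polygon"
"prob_A_nose","probability"
"prob_A_eye_left","probability"
"prob_A_eye_right","probability"
"prob_A_head","probability"
"prob_A_back","probability"
"prob_A_pelvis","probability"
"prob_A_anogenital","probability"
"prob_A_shoulder_left","probability"
"prob_A_shoulder_right","probability"
"prob_A_middle","probability"
"prob_A_tail_middle","probability"
"prob_A_tail_end","probability"
"prob_B_nose","probability"
"prob_B_eye_left","probability"
"prob_B_eye_right","probability"
"prob_B_head","probability"
"prob_B_back","probability"
"prob_B_pelvis","probability"
"prob_B_anogenital","probability"
"prob_B_shoulder_left","probability"
"prob_B_shoulder_right","probability"
"prob_B_middle","probability"
"prob_B_tail_middle","probability"
"prob_B_tail_end","probability"
"ctr_body_A_x","centroid"
"ctr_body_A_y","centroid"
"ctr_head_A_x","centroid"
"ctr_head_A_y","centroid"
"ctr_ag_A_x","centroid"
"ctr_ag_A_y","centroid"
"ctr_body_B_x","centroid"
"ctr_body_B_y","centroid"
"ctr_head_B_x","centroid"
"ctr_head_B_y","centroid"
"ctr_ag_B_x","centroid"
"ctr_ag_B_y","centroid"
"ctr_body_A_x_roll","centroid"
"ctr_body_A_y_roll","centroid"
"ctr_head_A_x_roll","centroid"
"ctr_head_A_y_roll","centroid"
"ctr_ag_A_x_roll","centroid"
"ctr_ag_A_y_roll","centroid"
"ctr_body_B_x_roll","centroid"
"ctr_body_B_y_roll","centroid"
"ctr_head_B_x_roll","centroid"
"ctr_head_B_y_roll","centroid"
"ctr_ag_B_x_roll","centroid"
"ctr_ag_B_y_roll","centroid"
"hull_body_A","hull"
"hull_head_A","hull"
"hull_body_B","hull"
"hull_head_B","hull"
"hull_body_A_roll","hull"
"hull_head_A_roll","hull"
"hull_body_B_roll","hull"
"hull_head_B_roll","hull"
"hull_body_A_ratio","hull"
"hull_body_B_ratio","hull"
"mov_body_A","movement"
"mov_head_A","movement"
"mov_ag_A","movement"
"mov_body_B","movement"
"mov_head_B","movement"
"mov_ag_B","movement"
"mov_body_A_roll","movement"
"mov_head_A_roll","movement"
"mov_ag_A_roll","movement"
"mov_body_B_roll","movement"
"mov_head_B_roll","movement"
"mov_ag_B_roll","movement"
"mov_total","movement"
"d_bodyA_bodyB","distance"
"d_bodyA_headB","distance"
"d_bodyA_agB","distance"
"d_headA_bodyB","distance"
"d_headA_headB","distance"
"d_headA_agB","distance"
"d_agA_bodyB","distance"
"d_agA_headB","distance"
"d_agA_agB","distance"
"d_bodyA_bodyB_roll","distance"
"d_bodyA_headB_roll","distance"
"d_bodyA_agB_roll","distance"
"d_headA_bodyB_roll","distance"
"d_headA_headB_roll","distance"
"d_headA_agB_roll","distance"
"d_agA_bodyB_roll","distance"
"d_agA_headB_roll","distance"
"d_agA_agB_roll","distance"
"d_min_centroids","distance"
"d_nose_nose","distance"
"d_noseA_agB","distance"
"d_noseB_agA","distance"
"within_nose_back_A","distance"
"within_headctr_agctr_A","distance"
"within_nose_tailend_A","distance"
"within_nose_back_B","distance"
"within_headctr_agctr_B","distance"
"within_nose_tailend_B","distance"
"elong_A","distance"
"elong_B","distance"
"ang_nose_head_back_A","angle"
"ang_head_back_pelvis_A","angle"
"ang_nose_head_back_B","angle"
"ang_head_back_pelvis_B","angle"
"prob_mean_A","probability"
"prob_min_A","probability"
"prob_mean_B","probability"
"prob_min_B","probability"
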