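# synthretarget kinematic tree, version 1
# World frame: right-handed, +z up, pelvis (root) at origin.
# Rest pose: supine on the bed plane, head toward +x, anatomical left toward +y.
# Columns: joint_name parent_name offset_x offset_y offset_z joint_limit_rad
# offsets in metres (child position relative to parent in the rest pose);
# joint_limit_rad bounds each axis-angle component for the pose generator.
pelvis - 0.00 0.00 0.00 0.30
left_hip pelvis 0.00 0.09 0.00 0.70
right_hip pelvis 0.00 -0.09 0.00 0.70
spine1 pelvis 0.12 0.00 0.00 0.25
left_knee left_hip -0.42 0.00 0.00 0.90
right_knee right_hip -0.42 0.00 0.00 0.90
spine2 spine1 0.13 0.00 0.00 0.25
left_ankle left_knee -0.42 0.00 0.00 0.40
right_ankle right_knee -0.42 0.00 0.00 0.40
spine3 spine2 0.13 0.00 0.00 0.25
left_foot left_ankle -0.04 0.00 0.12 0.30
right_foot right_ankle -0.04 0.00 0.12 0.30
neck spine3 0.10 0.00 0.00 0.40
left_collar spine3 0.05 0.08 0.00 0.20
right_collar spine3 0.05 -0.08 0.00 0.20
head neck 0.09 0.00 0.00 0.40
left_shoulder left_collar 0.00 0.10 0.00 0.90
right_shoulder right_collar 0.00 -0.10 0.00 0.90
left_elbow left_shoulder -0.28 0.02 0.00 1.00
right_elbow right_shoulder -0.28 -0.02 0.00 1.00
left_wrist left_elbow -0.26 0.01 0.00 0.50
right_wrist right_elbow -0.26 -0.01 0.00 0.50
nose head 0.05 0.00 0.10 0.00
left_eye head 0.06 0.03 0.09 0.00
right_eye head 0.06 -0.03 0.09 0.00
left_ear head 0.01 0.07 0.05 0.00
right_ear head 0.01 -0.07 0.05 0.00
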