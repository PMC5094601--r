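# Articulated 23-sphere macaque skeleton model.
#
# Units are metres; the rest pose is a quadrupedal stance on the floor plane
# z = 0 with the body axis along +x and the left side at +y. Sphere ids follow
# the numbering used throughout the package (jaw = 1, head = 3, chest = 6,
# abdomen = 8, hips = 9/10, elbows = 12/13, hands = 16/17, knees = 19/20,
# feet = 22/23). Joint bend limits are degrees between consecutive bone
# vectors (0 = chain continues straight); they are anatomically plausible
# defaults, not measured values, and are meant to be edited per subject.
# DOF counts are metadata describing the anatomical joint.
schema: skelfit-model/1
name: macaque_default
root: 8
spheres:
  - {id: 1,  label: jaw,        segment: head,       radius: 0.030, rest: [0.460,  0.000, 0.390]}
  - {id: 2,  label: neck,       segment: head,       radius: 0.040, rest: [0.345,  0.000, 0.380]}
  - {id: 3,  label: head,       segment: head,       radius: 0.050, rest: [0.400,  0.000, 0.430]}
  - {id: 4,  label: shoulder_l, segment: forelimb_l, radius: 0.040, rest: [0.260,  0.075, 0.317]}
  - {id: 5,  label: shoulder_r, segment: forelimb_r, radius: 0.040, rest: [0.260, -0.075, 0.317]}
  - {id: 6,  label: chest,      segment: trunk,      radius: 0.070, rest: [0.260,  0.000, 0.330]}
  - {id: 7,  label: spine,      segment: trunk,      radius: 0.065, rest: [0.130,  0.000, 0.315]}
  - {id: 8,  label: abdomen,    segment: trunk,      radius: 0.075, rest: [0.000,  0.000, 0.300]}
  - {id: 9,  label: hip_l,      segment: hindlimb_l, radius: 0.040, rest: [-0.100,  0.060, 0.270]}
  - {id: 10, label: hip_r,      segment: hindlimb_r, radius: 0.040, rest: [-0.100, -0.060, 0.270]}
  - {id: 11, label: pelvis,     segment: trunk,      radius: 0.060, rest: [-0.100,  0.000, 0.290]}
  - {id: 12, label: elbow_l,    segment: forelimb_l, radius: 0.030, rest: [0.260,  0.085, 0.190]}
  - {id: 13, label: elbow_r,    segment: forelimb_r, radius: 0.030, rest: [0.260, -0.085, 0.190]}
  - {id: 14, label: wrist_l,    segment: forelimb_l, radius: 0.025, rest: [0.270,  0.090, 0.070]}
  - {id: 15, label: wrist_r,    segment: forelimb_r, radius: 0.025, rest: [0.270, -0.090, 0.070]}
  - {id: 16, label: hand_l,     segment: forelimb_l, radius: 0.025, rest: [0.300,  0.090, 0.025]}
  - {id: 17, label: hand_r,     segment: forelimb_r, radius: 0.025, rest: [0.300, -0.090, 0.025]}
  - {id: 18, label: tail_base,  segment: tail,       radius: 0.030, rest: [-0.175,  0.000, 0.300]}
  - {id: 19, label: knee_l,     segment: hindlimb_l, radius: 0.030, rest: [-0.060,  0.070, 0.140]}
  - {id: 20, label: knee_r,     segment: hindlimb_r, radius: 0.030, rest: [-0.060, -0.070, 0.140]}
  - {id: 21, label: tail_tip,   segment: tail,       radius: 0.028, rest: [-0.250,  0.000, 0.320]}
  - {id: 22, label: foot_l,     segment: hindlimb_l, radius: 0.030, rest: [-0.110,  0.075, 0.030]}
  - {id: 23, label: foot_r,     segment: hindlimb_r, radius: 0.030, rest: [-0.110, -0.075, 0.030]}
joints:
  - {parent: 8,  child: 7,  dof: 3, bend: [0, 180]}
  - {parent: 7,  child: 6,  dof: 2, bend: [0, 75]}
  - {parent: 6,  child: 2,  dof: 3, bend: [0, 90]}
  - {parent: 2,  child: 3,  dof: 2, bend: [0, 90]}
  - {parent: 3,  child: 1,  dof: 2, bend: [20, 130]}
  - {parent: 6,  child: 4,  dof: 2, bend: [45, 135]}
  - {parent: 6,  child: 5,  dof: 2, bend: [45, 135]}
  - {parent: 4,  child: 12, dof: 3, bend: [10, 170]}
  - {parent: 5,  child: 13, dof: 3, bend: [10, 170]}
  - {parent: 12, child: 14, dof: 1, bend: [0, 150]}
  - {parent: 13, child: 15, dof: 1, bend: [0, 150]}
  - {parent: 14, child: 16, dof: 2, bend: [0, 80]}
  - {parent: 15, child: 17, dof: 2, bend: [0, 80]}
  - {parent: 8,  child: 11, dof: 3, bend: [0, 180]}
  - {parent: 11, child: 9,  dof: 2, bend: [45, 135]}
  - {parent: 11, child: 10, dof: 2, bend: [45, 135]}
  - {parent: 9,  child: 19, dof: 3, bend: [0, 175]}
  - {parent: 10, child: 20, dof: 3, bend: [0, 175]}
  - {parent: 19, child: 22, dof: 1, bend: [0, 150]}
  - {parent: 20, child: 23, dof: 1, bend: [0, 150]}
  - {parent: 11, child: 18, dof: 2, bend: [0, 90]}
  - {parent: 18, child: 21, dof: 2, bend: [0, 90]}
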