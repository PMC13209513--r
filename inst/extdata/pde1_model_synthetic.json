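{
  "name": "pde1-refined-7feat",
  "provenance": "Refined 7-feature PDE1 inhibitor pharmacophore. Kinds and tolerance radii follow the published refined model (two aromatic ring centers r=1.0, two H-bond acceptors r=0.7, one linking atom r=0.7, one aromatic/hydrophobic ring center r=1.0, one hydrophobic center r=1.0). The 3D centers are SYNTHETIC: the original model's coordinates were never published, so these were laid out on a plausible fused-ring inhibitor frame for reproducible testing.",
  "features": [
    {"label": "F1", "kind": "AROMATIC_RING", "center": [0.0, 0.0, 0.0], "radius": 1.0},
    {"label": "F2", "kind": "AROMATIC_RING", "center": [2.42, 0.3, 0.1], "radius": 1.0},
    {"label": "F3", "kind": "HBA", "center": [-0.9, 2.15, 0.25], "radius": 0.7},
    {"label": "F4", "kind": "HBA", "center": [3.1, 2.4, -0.2], "radius": 0.7},
    {"label": "F5", "kind": "LINKER", "center": [4.35, -1.1, 0.3], "radius": 0.7},
    {"label": "F6", "kind": "HYDROPHOBIC", "center": [6.75, -1.85, 0.55], "radius": 1.0},
    {"label": "F7", "kind": "HYDROPHOBIC", "center": [-2.6, -1.95, -0.4], "radius": 1.0}
  ]
}
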