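categories:
  Radiology:
    Ultrasound Imaging: [ultrasound, sonography, echography]
    Magnetic Resonance Imaging: [MRI, MR imaging]
    Computerized Tomography: [CT, CT scan, computed tomography]
    X-Ray: [xray, roentgenogram]
    2D Radiography: [radiography, radiograph]
    Angiography: [angiogram]
    PET: [positron emission tomography]
    Combined modalities in one image: [combined modalities]
    Coronarography: [coronary angiography]
    Cystography: []
    Scintigraphy: []
    Mammography: [mammogram]
    Bone Densitometry: [DEXA, bone density scan]
    Radiotherapy: [radiation therapy]
    Urography: [urogram]
    Pelvic Ultrasound: []
    Myelography: [myelogram]
    FibroScan: [transient elastography]
  Microscopy:
    Light Microscopy: []
    Electron Microscopy: []
    Transmission Microscopy: [transmission electron microscopy, TEM]
    Fluorescence Microscopy: []
    Biopsy: []
    Stool Microscopy: []
    Capillaroscopy: []
    Trophoblast Biopsy: [chorionic villus sampling]
    Cytology: [cytopathology]
  Visible light photography:
    Dermatology: []
    Skin: []
    Endoscopy: []
    Other organs: []
    Colposcopy: []
    Cystoscopy: []
    Hysteroscopy: []
  Printed signals and waves:
    Electroencephalography: [EEG]
    Electrocardiography: [ECG, EKG, electrocardiogram]
    Electromyography: [EMG]
    Holter: [holter monitor]
    Audiometry: [audiogram]
    Urodynamic Assessment: [urodynamics]
  Generic Biomedical Illustrations:
    modality tables and forms: []
    program listing: []
    statistical figures: []
    graphs: [graph]
    charts: [chart]
    screen shots: [screenshot, screenshots]
    flowcharts: [flowchart, flow chart]
    system overviews: [system overview]
    gene sequence: []
    chromatography: [chromatogram]
    gel: []
    chemical structure: []
    mathematics formula: [mathematical formula]
    non-clinical photos: [nonclinical photos]
    hand-drawn sketches: [sketch, sketches]
  Dimensionality:
    macro: []
    micro: []
    small: []
    gross: []
    combined dimensionality: []
  V-Spec:
    brown: []
    black: []
    white: []
    red: []
    gray: [grey]
    green: []
    yellow: []
    blue: []
    colored: [coloured]
  T-spec:
    finding: [findings]
    pathology: []
    differential diagnosis: []
    Amniocentesis: []
    Hemogram: [complete blood count, CBC]
    Non-Invasive Prenatal Screening: [NIPS, NIPT]
    Urinalysis: []
    Lumbar Puncture: [spinal tap]
    Seminogram: [semen analysis]
    Triple Test: []
  C-spec:
    Histology: [histopathology]
    Fracture: [fractures]
    Cancer: [carcinoma]
    Benign: []
    Malignant: [malignancy]
    Tumor: [tumour, neoplasm]
    Pregnancy: [pregnant]
    Antibiogramme: [antibiogram]
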