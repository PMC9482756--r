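codename,clearance_mm,calculated_mm,simulated_mm,experimental_mm
I,0.3,1.03,0.98,0.96
I,0.4,1.41,1.22,1.32
I,0.5,1.735,1.47,1.59
I,0.6,2.06,1.71,1.89
I,0.7,2.44,1.96,2.24
I,0.8,2.82,2.2,2.65
I,0.9,3.14,2.45,2.92
I,1,3.47,2.69,3.34
I,1.1,3.84,2.94,3.54
I,1.2,4.16,3.18,3.87
II,0.3,1.44,1.73,1.32
II,0.4,1.92,2.17,1.86
II,0.5,2.4,2.6,2.29
II,0.6,2.88,3.03,2.65
II,0.7,3.36,3.47,3.24
II,0.8,3.84,3.9,3.64
II,0.9,4.32,4.33,4.19
II,1,4.8,4.77,4.54
II,1.1,5.28,5.2,4.89
II,1.2,5.76,5.63,5.56
III,0.3,1.64,1.85,1.51
III,0.4,2.18,2.32,2.07
III,0.5,2.725,2.78,2.54
III,0.6,3.27,3.25,2.98
III,0.7,3.82,3.71,3.65
III,0.8,4.37,4.17,4.16
III,0.9,4.91,4.64,4.76
III,1,5.46,5.1,5.26
III,1.1,6,5.56,5.87
III,1.2,6.55,6.03,6.31
IV,0.3,0.36,0.41,0.33
IV,0.4,0.48,0.51,0.45
IV,0.5,0.6,0.61,0.64
IV,0.6,0.72,0.71,0.66
IV,0.7,0.84,0.81,0.79
IV,0.8,0.96,0.91,0.89
IV,0.9,1.08,1.02,1.18
IV,1,1.2,1.12,1.09
IV,1.1,1.32,1.22,1.24
IV,1.2,1.44,1.32,1.31
V,0.3,0.6,0.71,0.54
V,0.4,0.81,0.89,0.75
V,0.5,1.03,1.07,0.94
V,0.6,1.25,1.24,1.14
V,0.7,1.46,1.42,1.34
V,0.8,1.63,1.6,1.51
V,0.9,1.84,1.78,1.93
V,1,2.06,1.95,2.13
V,1.1,2.29,2.13,2.19
V,1.2,2.5,2.31,2.34
VI,0.3,0.99,1.08,0.91
VI,0.4,1.32,1.35,1.19
VI,0.5,1.65,1.62,1.51
VI,0.6,1.98,1.88,1.79
VI,0.7,2.31,2.15,2.24
VI,0.8,2.63,2.42,2.51
VI,0.9,2.96,2.69,3.11
VI,1,3.28,2.96,3.19
VI,1.1,3.62,3.23,3.47
VI,1.2,3.95,3.5,3.74
VII,0.3,1.51,1.76,1.44
VII,0.4,2.01,2.2,1.89
VII,0.5,2.51,2.64,2.31
VII,0.6,3.01,3.08,2.82
VII,0.7,3.51,3.52,3.38
VII,0.8,4.02,3.96,4.16
VII,0.9,4.52,4.4,4.38
VII,1,5.02,4.84,4.87
VII,1.1,5.52,5.28,5.39
VII,1.2,6.02,5.73,5.86
VIII,0.3,0.32,0.41,0.29
VIII,0.4,0.42,0.51,0.39
VIII,0.5,0.525,0.61,0.48
VIII,0.6,0.63,0.71,0.61
VIII,0.7,0.74,0.82,0.69
VIII,0.8,0.85,0.92,0.81
VIII,0.9,0.95,1.02,0.89
VIII,1,1.06,1.12,0.98
VIII,1.1,1.16,1.22,1.07
VIII,1.2,1.27,1.32,1.18
IX,0.3,0.54,0.61,0.49
IX,0.4,0.72,0.76,0.66
IX,0.5,0.9,0.91,0.94
IX,0.6,1.08,1.06,0.99
IX,0.7,1.26,1.21,1.18
IX,0.8,1.44,1.36,1.34
IX,0.9,1.62,1.52,1.48
IX,1,1.8,1.67,1.67
IX,1.1,1.98,1.82,1.83
IX,1.2,2.17,1.97,1.98
X,0.3,0.87,0.99,0.79
X,0.4,1.16,1.24,1.08
X,0.5,1.445,1.49,1.39
X,0.6,1.73,1.74,1.65
X,0.7,2.02,1.99,2.11
X,0.8,2.31,2.24,2.23
X,0.9,2.6,2.48,2.48
X,1,2.89,2.73,2.72
X,1.1,3.18,2.98,3.09
X,1.2,3.47,3.23,3.34
XI,0.3,1.32,1.69,1.22
XI,0.4,1.76,2.11,1.62
XI,0.5,2.2,2.53,2.08
XI,0.6,2.64,2.95,2.46
XI,0.7,3.08,3.37,2.89
XI,0.8,3.52,3.8,3.34
XI,0.9,3.96,4.22,3.79
XI,1,4.41,4.64,4.26
XI,1.1,4.85,5.06,4.97
XI,1.2,5.29,5.48,5.11
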