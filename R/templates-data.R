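# Idealized ribonucleotide templates (standard CCD ideal geometry),
# one row per heavy atom: base letter, atom name, x/y/z in Angstroms.
# OP3 (5'-terminal phosphate oxygen) is omitted; templates describe a
# chain-internal residue. Base atoms from these templates are grafted
# onto a reference structure during in silico base substitution, and
# whole residues are used by the synthetic-fixture generators.
.nt_templates <- local({
  base <- c("A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "A", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "G", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U", "U")
  atom <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4", "P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4", "P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6", "P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
  x <- c(1.024, 1.633, -0.183, 0.456, -0.520, -1.101, -0.064, -2.105, -3.445, -1.874, -3.065, -0.755, 0.158, 1.265, 1.843, 1.143, 1.290, 2.344, 0.391, -0.617, -0.792, 0.056, -0.911, -1.598, 0.325, -0.365, 0.542, 1.100, 0.033, 2.025, 3.395, 1.741, 2.927, 0.675, -0.297, -1.440, -2.066, -1.364, -1.556, -2.534, -0.626, 0.459, 1.384, 0.649, -0.226, 1.049, 1.692, -0.116, 0.415, -0.546, -1.189, -0.190, -2.178, -3.518, -2.001, -3.228, -0.924, -0.036, 0.652, 0.529, 1.467, 1.620, 2.464, 0.916, 0.087, -1.030, -1.679, 0.138, -0.399, 0.557, 1.197, 0.194, 2.181, 3.524, 1.995, 3.219, 0.922, 0.028, -0.690, -0.587, -1.515, -1.641, -2.391, -0.894, -0.070)
  y <- c(-0.137, 1.190, 0.005, -0.720, 0.209, -0.287, -0.383, 0.739, 0.360, 0.684, 0.271, -0.367, 0.029, 0.813, 0.963, 0.292, 0.091, 0.664, -0.656, -1.206, -1.051, -0.320, -0.277, 1.022, -0.105, -0.780, 0.217, -0.200, -0.318, 0.898, 0.582, 0.884, 0.560, -0.220, 0.162, 0.880, 1.037, 0.431, 0.279, 0.755, -0.401, -0.934, -1.626, -0.800, -0.134, -0.039, 1.237, 0.246, -0.733, 0.181, -0.419, -0.648, 0.583, 0.283, 0.373, -0.059, -0.729, -0.470, 0.683, 1.504, 0.945, 0.070, 0.350, -1.151, -1.399, 0.047, -1.228, -0.241, 0.736, -0.182, 0.415, 0.645, -0.588, -0.288, -0.383, 0.046, 0.723, 0.464, -0.671, -1.474, -0.936, -0.055, -0.292, 1.146, 1.384)
  z <- c(-4.723, -4.488, -5.778, -3.334, -2.863, -1.538, -0.538, -0.969, -1.287, 0.558, 1.231, 0.729, 1.803, 1.672, 2.828, 3.773, 5.156, 5.846, 5.787, 5.136, 3.841, 3.126, 5.008, 4.844, 6.025, 3.580, 3.109, 1.748, 0.782, 1.182, 1.439, -0.338, -1.066, -0.507, -1.534, -1.334, -2.464, -3.453, -4.846, -5.397, -5.551, -4.923, -5.664, -3.630, -2.868, -4.028, -3.646, -5.102, -2.721, -2.193, -0.942, 0.076, -0.307, -0.703, 1.215, 1.806, 1.317, 2.453, 2.514, 1.620, 3.535, 4.520, 5.569, 4.483, 3.442, -4.037, -3.660, -5.107, -2.726, -2.196, -0.942, 0.074, -0.301, -0.686, 1.218, 1.819, 1.319, 2.451, 2.486, 1.580, 3.517, 4.530, 5.460, 4.502, 3.459)
  data.frame(base = base, atom = atom, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
})
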