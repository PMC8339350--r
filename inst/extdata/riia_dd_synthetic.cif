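data_riia_dd_synthetic
#
_entry.id riia_dd_synthetic
#
_cell.length_a    45.000
_cell.length_b    45.000
_cell.length_c    60.000
_cell.angle_alpha 90.00
_cell.angle_beta  90.00
_cell.angle_gamma 90.00
#
_symmetry.space_group_name_H-M 'P 1'
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1 C CA . GLY A 1 1 ? 2.300 0.000 0.000 1.00 20.00 ? 1 GLY A CA 1
ATOM 2 C CA . GLN A 1 2 ? -0.399 2.265 1.500 1.00 20.00 ? 2 GLN A CA 1
ATOM 3 C CA . LEU A 1 3 ? -2.162 -0.785 3.000 1.00 20.00 ? 3 LEU A CA 1
ATOM 4 C CA . LEU A 1 4 ? 1.148 -1.993 4.500 1.00 20.00 ? 4 LEU A CA 1
ATOM 5 C CA . ARG A 1 5 ? 1.764 1.476 6.000 1.00 20.00 ? 5 ARG A CA 1
ATOM 6 C CA . GLU A 1 6 ? -1.759 1.481 7.500 1.00 20.00 ? 6 GLU A CA 1
ATOM 7 C CA . LEU A 1 7 ? -1.154 -1.990 9.000 1.00 20.00 ? 7 LEU A CA 1
ATOM 8 C CA . VAL A 1 8 ? 2.159 -0.792 10.500 1.00 20.00 ? 8 VAL A CA 1
ATOM 9 C CA . ASN A 1 9 ? 0.405 2.264 12.000 1.00 20.00 ? 9 ASN A CA 1
ATOM 10 C CA . GLU A 1 10 ? -2.300 0.007 13.500 1.00 20.00 ? 10 GLU A CA 1
ATOM 11 C CA . ILE A 1 11 ? 0.392 -2.266 15.000 1.00 20.00 ? 11 ILE A CA 1
ATOM 12 C CA . ALA A 1 12 ? 2.164 0.779 16.500 1.00 20.00 ? 12 ALA A CA 1
ATOM 13 C CA . PRO A 1 13 ? 2.300 0.000 17.700 1.00 20.00 ? 13 PRO A CA 1
ATOM 14 C CA . ALA A 1 14 ? 3.800 1.683 17.148 1.00 20.00 ? 14 ALA A CA 1
ATOM 15 C CA . SER A 1 15 ? 5.300 1.819 16.001 1.00 20.00 ? 15 SER A CA 1
ATOM 16 C CA . LEU A 1 16 ? 6.800 0.282 15.312 1.00 20.00 ? 16 LEU A CA 1
ATOM 17 C CA . GLU A 1 17 ? 8.300 -1.514 15.716 1.00 20.00 ? 17 GLU A CA 1
ATOM 18 C CA . ALA A 1 18 ? 8.043 2.091 16.500 1.00 20.00 ? 18 ALA A CA 1
ATOM 19 C CA . VAL A 1 19 ? 7.106 -1.305 15.000 1.00 20.00 ? 19 VAL A CA 1
ATOM 20 C CA . GLU A 1 20 ? 10.614 -1.639 13.500 1.00 20.00 ? 20 GLU A CA 1
ATOM 21 C CA . TYR A 1 21 ? 10.334 1.873 12.000 1.00 20.00 ? 21 TYR A CA 1
ATOM 22 C CA . PHE A 1 22 ? 6.924 0.990 10.500 1.00 20.00 ? 22 PHE A CA 1
ATOM 23 C CA . LYS A 1 23 ? 8.385 -2.216 9.000 1.00 20.00 ? 23 LYS A CA 1
ATOM 24 C CA . ARG A 1 24 ? 11.289 -0.221 7.500 1.00 20.00 ? 24 ARG A CA 1
ATOM 25 C CA . LEU A 1 25 ? 8.821 2.293 6.000 1.00 20.00 ? 25 LEU A CA 1
ATOM 26 C CA . LEU A 1 26 ? 6.773 -0.574 4.500 1.00 20.00 ? 26 LEU A CA 1
ATOM 27 C CA . HIS A 1 27 ? 9.951 -2.094 3.000 1.00 20.00 ? 27 HIS A CA 1
ATOM 28 C CA . GLU A 1 28 ? 10.898 1.300 1.500 1.00 20.00 ? 28 GLU A CA 1
ATOM 29 C CA . ALA A 1 29 ? 7.391 1.644 0.000 1.00 20.00 ? 29 ALA A CA 1
ATOM 30 C CA . ALA A 1 30 ? 7.660 -1.869 -1.500 1.00 20.00 ? 30 ALA A CA 1
ATOM 31 C CA . THR A 1 31 ? 11.000 0.000 -2.000 1.00 20.00 ? 31 THR A CA 1
ATOM 32 C CA . ALA A 1 32 ? 14.040 1.933 -2.240 1.00 20.00 ? 32 ALA A CA 1
ATOM 33 C CA . TYR A 1 33 ? 17.080 2.956 -2.480 1.00 20.00 ? 33 TYR A CA 1
ATOM 34 C CA . SER A 1 34 ? 20.120 2.590 -2.720 1.00 20.00 ? 34 SER A CA 1
ATOM 35 C CA . THR A 1 35 ? 23.160 1.005 -2.960 1.00 20.00 ? 35 THR A CA 1
ATOM 36 C CA . ASP A 1 36 ? 26.200 -1.052 -3.200 1.00 20.00 ? 36 ASP A CA 1
ATOM 37 C CA . GLU A 1 37 ? 29.240 -2.615 -3.440 1.00 20.00 ? 37 GLU A CA 1
ATOM 38 C CA . ARG A 1 38 ? 32.280 -2.947 -3.680 1.00 20.00 ? 38 ARG A CA 1
ATOM 39 C CA . LEU A 1 39 ? 35.320 -1.894 -3.920 1.00 20.00 ? 39 LEU A CA 1
ATOM 40 C CA . GLU A 1 40 ? 38.360 0.050 -4.160 1.00 20.00 ? 40 GLU A CA 1
ATOM 41 C CA . TRP A 1 41 ? 41.400 1.971 -4.400 1.00 20.00 ? 41 TRP A CA 1
ATOM 42 C CA . ALA A 1 42 ? 44.440 2.965 -4.640 1.00 20.00 ? 42 ALA A CA 1
ATOM 43 C CA . MET A 1 43 ? 47.480 2.564 -4.880 1.00 20.00 ? 43 MET A CA 1
ATOM 44 C CA . SER A 1 44 ? 50.520 0.957 -5.120 1.00 20.00 ? 44 SER A CA 1
ATOM 45 C CA . GLY B 1 1 ? 6.800 0.500 16.000 1.00 20.00 ? 1 GLY B CA 1
ATOM 46 C CA . GLN B 1 2 ? 4.101 -1.765 14.500 1.00 20.00 ? 2 GLN B CA 1
ATOM 47 C CA . LEU B 1 3 ? 2.338 1.285 13.000 1.00 20.00 ? 3 LEU B CA 1
ATOM 48 C CA . LEU B 1 4 ? 5.648 2.493 11.500 1.00 20.00 ? 4 LEU B CA 1
ATOM 49 C CA . ARG B 1 5 ? 6.264 -0.976 10.000 1.00 20.00 ? 5 ARG B CA 1
ATOM 50 C CA . GLU B 1 6 ? 2.741 -0.981 8.500 1.00 20.00 ? 6 GLU B CA 1
ATOM 51 C CA . LEU B 1 7 ? 3.346 2.490 7.000 1.00 20.00 ? 7 LEU B CA 1
ATOM 52 C CA . VAL B 1 8 ? 6.659 1.292 5.500 1.00 20.00 ? 8 VAL B CA 1
ATOM 53 C CA . ASN B 1 9 ? 4.905 -1.764 4.000 1.00 20.00 ? 9 ASN B CA 1
ATOM 54 C CA . GLU B 1 10 ? 2.200 0.493 2.500 1.00 20.00 ? 10 GLU B CA 1
ATOM 55 C CA . ILE B 1 11 ? 4.892 2.766 1.000 1.00 20.00 ? 11 ILE B CA 1
ATOM 56 C CA . ALA B 1 12 ? 6.664 -0.279 -0.500 1.00 20.00 ? 12 ALA B CA 1
ATOM 57 C CA . PRO B 1 13 ? 6.800 0.500 -1.700 1.00 20.00 ? 13 PRO B CA 1
ATOM 58 C CA . ALA B 1 14 ? 8.300 -1.183 -1.148 1.00 20.00 ? 14 ALA B CA 1
ATOM 59 C CA . SER B 1 15 ? 9.800 -1.319 -0.001 1.00 20.00 ? 15 SER B CA 1
ATOM 60 C CA . LEU B 1 16 ? 11.300 0.218 0.688 1.00 20.00 ? 16 LEU B CA 1
ATOM 61 C CA . GLU B 1 17 ? 12.800 2.014 0.284 1.00 20.00 ? 17 GLU B CA 1
ATOM 62 C CA . ALA B 1 18 ? 12.543 -1.591 -0.500 1.00 20.00 ? 18 ALA B CA 1
ATOM 63 C CA . VAL B 1 19 ? 11.606 1.805 1.000 1.00 20.00 ? 19 VAL B CA 1
ATOM 64 C CA . GLU B 1 20 ? 15.114 2.139 2.500 1.00 20.00 ? 20 GLU B CA 1
ATOM 65 C CA . TYR B 1 21 ? 14.834 -1.373 4.000 1.00 20.00 ? 21 TYR B CA 1
ATOM 66 C CA . PHE B 1 22 ? 11.424 -0.490 5.500 1.00 20.00 ? 22 PHE B CA 1
ATOM 67 C CA . LYS B 1 23 ? 12.885 2.716 7.000 1.00 20.00 ? 23 LYS B CA 1
ATOM 68 C CA . ARG B 1 24 ? 15.789 0.721 8.500 1.00 20.00 ? 24 ARG B CA 1
ATOM 69 C CA . LEU B 1 25 ? 13.321 -1.793 10.000 1.00 20.00 ? 25 LEU B CA 1
ATOM 70 C CA . LEU B 1 26 ? 11.273 1.074 11.500 1.00 20.00 ? 26 LEU B CA 1
ATOM 71 C CA . HIS B 1 27 ? 14.451 2.594 13.000 1.00 20.00 ? 27 HIS B CA 1
ATOM 72 C CA . GLU B 1 28 ? 15.398 -0.800 14.500 1.00 20.00 ? 28 GLU B CA 1
ATOM 73 C CA . ALA B 1 29 ? 11.891 -1.144 16.000 1.00 20.00 ? 29 ALA B CA 1
ATOM 74 C CA . ALA B 1 30 ? 12.160 2.369 17.500 1.00 20.00 ? 30 ALA B CA 1
ATOM 75 C CA . THR B 1 31 ? 15.500 0.500 18.000 1.00 20.00 ? 31 THR B CA 1
ATOM 76 C CA . ALA B 1 32 ? 18.540 -1.433 18.240 1.00 20.00 ? 32 ALA B CA 1
ATOM 77 C CA . TYR B 1 33 ? 21.580 -2.456 18.480 1.00 20.00 ? 33 TYR B CA 1
ATOM 78 C CA . SER B 1 34 ? 24.620 -2.090 18.720 1.00 20.00 ? 34 SER B CA 1
ATOM 79 C CA . THR B 1 35 ? 27.660 -0.505 18.960 1.00 20.00 ? 35 THR B CA 1
ATOM 80 C CA . ASP B 1 36 ? 30.700 1.552 19.200 1.00 20.00 ? 36 ASP B CA 1
ATOM 81 C CA . GLU B 1 37 ? 33.740 3.115 19.440 1.00 20.00 ? 37 GLU B CA 1
ATOM 82 C CA . ARG B 1 38 ? 36.780 3.447 19.680 1.00 20.00 ? 38 ARG B CA 1
ATOM 83 C CA . LEU B 1 39 ? 39.820 2.394 19.920 1.00 20.00 ? 39 LEU B CA 1
ATOM 84 C CA . GLU B 1 40 ? 42.860 0.450 20.160 1.00 20.00 ? 40 GLU B CA 1
ATOM 85 C CA . TRP B 1 41 ? 45.900 -1.471 20.400 1.00 20.00 ? 41 TRP B CA 1
ATOM 86 C CA . ALA B 1 42 ? 48.940 -2.465 20.640 1.00 20.00 ? 42 ALA B CA 1
ATOM 87 C CA . MET B 1 43 ? 51.980 -2.064 20.880 1.00 20.00 ? 43 MET B CA 1
ATOM 88 C CA . SER B 1 44 ? 55.020 -0.457 21.120 1.00 20.00 ? 44 SER B CA 1
#
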