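#------------------------------------------------------------------------------
# Synthetic magnetite (Fe3O4) inverse-spinel unit cell, Fd-3m origin choice 2.
# Packaged stand-in emulating the COD magnetite entry (cubic spinel,
# a = 8.3958 A, Fe on 8a tetrahedral and 16d octahedral Wyckoff sites,
# O on 32e, u = 0.2549). Symmetry operators generated from the Fd-3m:2
# generator set and verified for group closure (192 ops) and Wyckoff
# multiplicities 8/16/32. SYNTHETIC fixture, not a COD download.
#------------------------------------------------------------------------------
data_magnetite_synthetic
_chemical_formula_sum              'Fe3 O4'
_chemical_name_mineral             Magnetite
_space_group_name_H-M_alt          'F d -3 m :2'
_space_group_IT_number             227
_cell_length_a                     8.3958
_cell_length_b                     8.3958
_cell_length_c                     8.3958
_cell_angle_alpha                  90
_cell_angle_beta                   90
_cell_angle_gamma                  90
_cell_volume                       591.83
loop_
_space_group_symop_operation_xyz
  '-x,-y,-z'
  '-x,-z,-y'
  '-x,1/2-y,1/2-z'
  '-x,1/2-z,1/2-y'
  '-x,1/4+y,1/4+z'
  '-x,1/4+z,1/4+y'
  '-x,3/4+y,3/4+z'
  '-x,3/4+z,3/4+y'
  '-y,-x,-z'
  '-y,-z,-x'
  '-y,1/2-x,1/2-z'
  '-y,1/2-z,1/2-x'
  '-y,1/4+x,1/4+z'
  '-y,1/4+z,1/4+x'
  '-y,3/4+x,3/4+z'
  '-y,3/4+z,3/4+x'
  '-z,-x,-y'
  '-z,-y,-x'
  '-z,1/2-x,1/2-y'
  '-z,1/2-y,1/2-x'
  '-z,1/4+x,1/4+y'
  '-z,1/4+y,1/4+x'
  '-z,3/4+x,3/4+y'
  '-z,3/4+y,3/4+x'
  '1/2+x,1/2+y,z'
  '1/2+x,1/2+z,y'
  '1/2+x,1/4-y,3/4-z'
  '1/2+x,1/4-z,3/4-y'
  '1/2+x,3/4-y,1/4-z'
  '1/2+x,3/4-z,1/4-y'
  '1/2+x,y,1/2+z'
  '1/2+x,z,1/2+y'
  '1/2+y,1/2+x,z'
  '1/2+y,1/2+z,x'
  '1/2+y,1/4-x,3/4-z'
  '1/2+y,1/4-z,3/4-x'
  '1/2+y,3/4-x,1/4-z'
  '1/2+y,3/4-z,1/4-x'
  '1/2+y,x,1/2+z'
  '1/2+y,z,1/2+x'
  '1/2+z,1/2+x,y'
  '1/2+z,1/2+y,x'
  '1/2+z,1/4-x,3/4-y'
  '1/2+z,1/4-y,3/4-x'
  '1/2+z,3/4-x,1/4-y'
  '1/2+z,3/4-y,1/4-x'
  '1/2+z,x,1/2+y'
  '1/2+z,y,1/2+x'
  '1/2-x,-y,1/2-z'
  '1/2-x,-z,1/2-y'
  '1/2-x,1/2-y,-z'
  '1/2-x,1/2-z,-y'
  '1/2-x,1/4+y,3/4+z'
  '1/2-x,1/4+z,3/4+y'
  '1/2-x,3/4+y,1/4+z'
  '1/2-x,3/4+z,1/4+y'
  '1/2-y,-x,1/2-z'
  '1/2-y,-z,1/2-x'
  '1/2-y,1/2-x,-z'
  '1/2-y,1/2-z,-x'
  '1/2-y,1/4+x,3/4+z'
  '1/2-y,1/4+z,3/4+x'
  '1/2-y,3/4+x,1/4+z'
  '1/2-y,3/4+z,1/4+x'
  '1/2-z,-x,1/2-y'
  '1/2-z,-y,1/2-x'
  '1/2-z,1/2-x,-y'
  '1/2-z,1/2-y,-x'
  '1/2-z,1/4+x,3/4+y'
  '1/2-z,1/4+y,3/4+x'
  '1/2-z,3/4+x,1/4+y'
  '1/2-z,3/4+y,1/4+x'
  '1/4+x,-y,1/4+z'
  '1/4+x,-z,1/4+y'
  '1/4+x,1/2-y,3/4+z'
  '1/4+x,1/2-z,3/4+y'
  '1/4+x,1/4+y,-z'
  '1/4+x,1/4+z,-y'
  '1/4+x,3/4+y,1/2-z'
  '1/4+x,3/4+z,1/2-y'
  '1/4+y,-x,1/4+z'
  '1/4+y,-z,1/4+x'
  '1/4+y,1/2-x,3/4+z'
  '1/4+y,1/2-z,3/4+x'
  '1/4+y,1/4+x,-z'
  '1/4+y,1/4+z,-x'
  '1/4+y,3/4+x,1/2-z'
  '1/4+y,3/4+z,1/2-x'
  '1/4+z,-x,1/4+y'
  '1/4+z,-y,1/4+x'
  '1/4+z,1/2-x,3/4+y'
  '1/4+z,1/2-y,3/4+x'
  '1/4+z,1/4+x,-y'
  '1/4+z,1/4+y,-x'
  '1/4+z,3/4+x,1/2-y'
  '1/4+z,3/4+y,1/2-x'
  '1/4-x,1/2+y,3/4-z'
  '1/4-x,1/2+z,3/4-y'
  '1/4-x,1/4-y,z'
  '1/4-x,1/4-z,y'
  '1/4-x,3/4-y,1/2+z'
  '1/4-x,3/4-z,1/2+y'
  '1/4-x,y,1/4-z'
  '1/4-x,z,1/4-y'
  '1/4-y,1/2+x,3/4-z'
  '1/4-y,1/2+z,3/4-x'
  '1/4-y,1/4-x,z'
  '1/4-y,1/4-z,x'
  '1/4-y,3/4-x,1/2+z'
  '1/4-y,3/4-z,1/2+x'
  '1/4-y,x,1/4-z'
  '1/4-y,z,1/4-x'
  '1/4-z,1/2+x,3/4-y'
  '1/4-z,1/2+y,3/4-x'
  '1/4-z,1/4-x,y'
  '1/4-z,1/4-y,x'
  '1/4-z,3/4-x,1/2+y'
  '1/4-z,3/4-y,1/2+x'
  '1/4-z,x,1/4-y'
  '1/4-z,y,1/4-x'
  '3/4+x,-y,3/4+z'
  '3/4+x,-z,3/4+y'
  '3/4+x,1/2-y,1/4+z'
  '3/4+x,1/2-z,1/4+y'
  '3/4+x,1/4+y,1/2-z'
  '3/4+x,1/4+z,1/2-y'
  '3/4+x,3/4+y,-z'
  '3/4+x,3/4+z,-y'
  '3/4+y,-x,3/4+z'
  '3/4+y,-z,3/4+x'
  '3/4+y,1/2-x,1/4+z'
  '3/4+y,1/2-z,1/4+x'
  '3/4+y,1/4+x,1/2-z'
  '3/4+y,1/4+z,1/2-x'
  '3/4+y,3/4+x,-z'
  '3/4+y,3/4+z,-x'
  '3/4+z,-x,3/4+y'
  '3/4+z,-y,3/4+x'
  '3/4+z,1/2-x,1/4+y'
  '3/4+z,1/2-y,1/4+x'
  '3/4+z,1/4+x,1/2-y'
  '3/4+z,1/4+y,1/2-x'
  '3/4+z,3/4+x,-y'
  '3/4+z,3/4+y,-x'
  '3/4-x,1/2+y,1/4-z'
  '3/4-x,1/2+z,1/4-y'
  '3/4-x,1/4-y,1/2+z'
  '3/4-x,1/4-z,1/2+y'
  '3/4-x,3/4-y,z'
  '3/4-x,3/4-z,y'
  '3/4-x,y,3/4-z'
  '3/4-x,z,3/4-y'
  '3/4-y,1/2+x,1/4-z'
  '3/4-y,1/2+z,1/4-x'
  '3/4-y,1/4-x,1/2+z'
  '3/4-y,1/4-z,1/2+x'
  '3/4-y,3/4-x,z'
  '3/4-y,3/4-z,x'
  '3/4-y,x,3/4-z'
  '3/4-y,z,3/4-x'
  '3/4-z,1/2+x,1/4-y'
  '3/4-z,1/2+y,1/4-x'
  '3/4-z,1/4-x,1/2+y'
  '3/4-z,1/4-y,1/2+x'
  '3/4-z,3/4-x,y'
  '3/4-z,3/4-y,x'
  '3/4-z,x,3/4-y'
  '3/4-z,y,3/4-x'
  'x,1/2+y,1/2+z'
  'x,1/2+z,1/2+y'
  'x,1/4-y,1/4-z'
  'x,1/4-z,1/4-y'
  'x,3/4-y,3/4-z'
  'x,3/4-z,3/4-y'
  'x,y,z'
  'x,z,y'
  'y,1/2+x,1/2+z'
  'y,1/2+z,1/2+x'
  'y,1/4-x,1/4-z'
  'y,1/4-z,1/4-x'
  'y,3/4-x,3/4-z'
  'y,3/4-z,3/4-x'
  'y,x,z'
  'y,z,x'
  'z,1/2+x,1/2+y'
  'z,1/2+y,1/2+x'
  'z,1/4-x,1/4-y'
  'z,1/4-y,1/4-x'
  'z,3/4-x,3/4-y'
  'z,3/4-y,3/4-x'
  'z,x,y'
  'z,y,x'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
Fe1_tet Fe 0.12500 0.12500 0.12500
Fe2_oct Fe 0.50000 0.50000 0.50000
O1      O  0.25490 0.25490 0.25490
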