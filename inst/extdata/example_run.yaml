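# Full mapping run: volume + mesh in, material-annotated deck out.
# Paths are relative to where you invoke the tool.
volume:
  path: shell.nii       # .nii/.nii.gz, raw+.json sidecar, or a DICOM dir
  format: auto
mesh:
  path: shell.inp       # Abaqus deck with *NODE and *ELEMENT (C3D4)
chain: bonemat_test_eq11_13   # builtin name, or {file: my_chain.yaml}
mapping:
  strategy: volume_integration  # node_average | voxel_average | volume_integration
  refinement: 2                 # 8^refinement samples per element
  oob: clamp                    # clamp (counted) | error
  voxel_fallback: integration   # for elements with no interior voxel center
  average: hu                   # hu (convert the mean) | modulus (mean of E)
  transform:                    # rigid mesh -> CT-world alignment
    rotation: [1, 0, 0, 0, 1, 0, 0, 0, 1]
    translation: [0.0, 0.0, 0.0]
binning:
  n_bins: 50
  space: modulus                # modulus | hu
  statistic: volume_weighted_mean   # or midpoint
poisson_ratio: 0.3
output:
  inp: mapped.inp
  vtk: mapped.vtk
  csv: elements.csv
  report: report.yaml
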