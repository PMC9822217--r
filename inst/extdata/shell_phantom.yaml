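# Bone-like phantom: high-HU cortical shell around a low-HU trabecular
# interior, plus a structured box mesh covering it. Use with:
#   Rscript inst/cli/bonemapr.R phantom --spec shell_phantom.yaml \
#     --out-volume shell.nii --out-mesh shell.inp
kind: shell
dims: [27, 27, 27]
spacing: [1.0, 1.0, 1.0]
origin: [-13.0, -13.0, -13.0]
center: [0.0, 0.0, 0.0]
r_inner: 6.0
r_outer: 10.0
hu_shell: 1500.0
hu_interior: 300.0
hu_background: 0.0
mesh:
  extent: [20.0, 20.0, 20.0]
  divisions: [10, 10, 10]
  origin: [-10.0, -10.0, -10.0]
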