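# Example pipeline configuration: the bundled bioreactor operating point.
# Run with:  Rscript inst/cli/trabeflow.R report --config this_file.yaml
seed: 1
scaffold:
  porosity_target: 0.90
  tbth_target: 120.7     # um
  pore_mean: 839         # um
  spacing: 40            # um voxels
  domain_size: [4000, 4000, 4000]
fluid:
  viscosity: 6.913e-4    # Pa s (water, 37 C)
  density: 993           # kg/m3
cartridge:
  scaffold_length: 9.0e-3   # m (three 3 mm scaffolds)
  cartridge_area: 78.5e-6   # m2
  cartridge_diameter: 10.4e-3
  tubing_diameter: 3.2e-3
flow:
  mL_min: 1.7
solver:
  tol: 1.0e-4
  max_iter: 30000
  buffer: 8
  inlet: superficial_velocity
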