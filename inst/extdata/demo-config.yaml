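# Demo pipeline configuration: a small synthetic two-hemisphere connectome,
# short simulations. Run with:
#   runPipeline(system.file("extdata", "demo-config.yaml", package = "conndyn"),
#               subcommand = "all", outDir = "demo-out")
connectome:
  synthetic:
    nRegions: 30
    density: 0.2
    nModules: 7
    gradientStrength: 1
    seed: 1
w_grid:
  from: 0.0
  to: 1.0
  by: 0.05
duration: 60
dt: 0.01
ddm:
  nTrials: 500
seed: 1
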