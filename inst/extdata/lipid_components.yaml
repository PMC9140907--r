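# Component scattering length densities (SLD, 10^-6 A^-2) and molecular
# volumes (A^3) of the lipid species handled by memscatter.
#
# These are literature defaults, NOT values from any single study: SLDs are
# computed from standard coherent scattering lengths (C 6.646 fm, H -3.739 fm,
# D 6.671 fm, O 5.803 fm) and published fluid-phase molecular volumes
# (PC headgroup ~319 A^3; POPC tails ~937 A^3; cholesterol ~630 A^3).
# Every number can be overridden by passing a modified species table.
#
# n_pc_tails: number of glycerophospholipid acyl chains (0 for cholesterol).
# n_dha_tails: how many of those chains are docosahexaenoyl (22:6).
species:
  POPC:
    head_sld: 1.88
    tail_sld: -0.28
    head_volume: 319
    tail_volume: 937
    n_pc_tails: 2
    n_dha_tails: 0
  d31-POPC:            # palmitoyl chain perdeuterated; used in reflectometry samples
    head_sld: 1.88
    tail_sld: 3.16
    head_volume: 319
    tail_volume: 937
    n_pc_tails: 2
    n_dha_tails: 0
  18:0-22:6PC:         # hybrid: stearoyl + docosahexaenoyl
    head_sld: 1.88
    tail_sld: 0.06
    head_volume: 319
    tail_volume: 970
    n_pc_tails: 2
    n_dha_tails: 1
  22:6-22:6PC:         # symmetric di-DHA
    head_sld: 1.88
    tail_sld: 0.48
    head_volume: 319
    tail_volume: 995
    n_pc_tails: 2
    n_dha_tails: 2
  cholesterol:
    head_sld: 0.21     # hydroxyl/ring start lumped with the ring body SLD
    tail_sld: 0.21
    head_volume: 30
    tail_volume: 600
    n_pc_tails: 0
    n_dha_tails: 0
solvents:
  D2O:
    sld: 6.35
    d2o_volume_fraction: 1.0
  H2O:
    sld: -0.56
    d2o_volume_fraction: 0.0
  SiMW:                # silicon-matched water, defined by its D2O volume fraction
    d2o_volume_fraction: 0.38
substrate:
  silicon_sld: 2.07
  oxide_sld: 3.47
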