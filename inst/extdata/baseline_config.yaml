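# Reference configuration: soft matrix, closed oxygen domain, overlapping
# go-or-grow switch, constant matrix permeability.  Any sim_params field can
# be set here; unknown keys are rejected.  The scenario key applies a preset
# before the explicit overrides below.
scenario: baseline
E_ECM: 1000        # Pa
nu_ECM: 0.13
n0: 4.0            # mg/L
R0: 0.25           # mm
C_init: 7.0e4      # cells/mm^3
R_dom: 1.5         # mm
dr: 5.0e-3         # mm
dt: 2.0e-4         # day
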