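# shared fixtures: a mid-sized loop and two wires used across the suite
test_geom <- function() tloop_geometry(R_mm = 1, y_mm = 8, w_mm = 6, h_mm = 10)

wire_IV <- function() lookup_archwire("IV")
wire_I <- function() lookup_archwire("I")

# a custom wire with unit bending stiffness keeps hand calculations easy
unit_wire <- function() list(E_Pa = 1, I_z_m4 = 1)
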